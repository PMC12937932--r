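test_that("feature assembly yields the documented column count and names", {
  fx <- small_cohort_features()
  tab <- fx$table
  # 2*23 kinematic + 23*22/2 adjacency + 7*23 local + 9 global
  expect_equal(ncol(tab$values), 46 + 253 + 161 + 9)
  expect_false(any(duplicated(colnames(tab$values))))
  expect_true(all(c("pos_Pelvis", "vel_Right Foot", "A_Pelvis_L5",
                    "eigenvector_Neck", "strength_Head",
                    "clustering_Left Forearm", "global_avg_clustering") %in%
                    colnames(tab$values)))
  # adjacency features are pass-throughs of the network entries
  expect_equal(unname(tab$values["S002", "A_Pelvis_Head"]),
               fx$nets[["S002"]]$A["Pelvis", "Head"])
  # subject mismatch is detected
  expect_error(assemble_features(fx$kin[-1], fx$nets, fx$gms),
               "subject sets differ")
})

test_that("a 3-segment toy table has 39 columns", {
  fx <- small_cohort_features()
  kin3 <- lapply(fx$kin, function(k) {
    k$features <- k$features[1:3, ]
    k$magnitudes <- k$magnitudes[1:3]
    k
  })
  nets3 <- lapply(kin3, function(k) build_network(k$magnitudes))
  gms3 <- lapply(nets3, metrics_across_thresholds)
  tab3 <- assemble_features(kin3, nets3, gms3)
  expect_equal(ncol(tab3$values), 6 + 3 + 21 + 9)
})

test_that("residualization removes linear age/sex structure exactly", {
  set.seed(12)
  n <- 40
  age <- runif(n, 40, 80); sex <- rbinom(n, 1, 0.5)
  V <- cbind(
    lin = 2 * age + 1,
    orth = rnorm(n),
    mix = 3 * age - 2 * sex + rnorm(n, 0, 0.1)
  )
  V[, "orth"] <- V[, "orth"] - lm(V[, "orth"] ~ age + sex)$fitted.values +
    mean(V[, "orth"])
  tab <- structure(list(subjects = as.character(1:n), values = V,
                        residualized = FALSE, standardized = FALSE),
                   class = "FeatureTable")
  res <- residualize(tab, age, sex)
  expect_lt(max(abs(res$values[, "lin"])), 1e-9)
  # feature orthogonal to the design: residuals = centered values
  expect_equal(res$values[, "orth"],
               V[, "orth"] - mean(V[, "orth"]), tolerance = 1e-9)
  # hand-written normal-equations oracle for the fitted coefficients
  D <- cbind(1, age, sex)
  beta <- solve(t(D) %*% D, t(D) %*% V[, "mix"])
  se <- sqrt(diag(solve(t(D) %*% D)) *
               sum((V[, "mix"] - D %*% beta)^2) / (n - 3))
  expect_lt(abs(beta[2] - 3), 3 * se[2])
  expect_lt(abs(beta[3] + 2), 3 * se[3])
  expect_equal(res$values[, "mix"], V[, "mix"] - as.numeric(D %*% beta),
               tolerance = 1e-9)
})

test_that("cleaning applies the missingness, imputation, variance and scaling rules", {
  V <- cbind(
    mostly_missing = c(rep(NA, 17), 1, 2, 3),
    constant = rep(7, 20),
    gap = c(1, 2, NA, 3, rnorm(16))
  )
  rownames(V) <- paste0("s", 1:20)
  tab <- structure(list(subjects = rownames(V), values = V,
                        residualized = FALSE, standardized = FALSE),
                   class = "FeatureTable")
  out <- clean_features(tab)
  expect_setequal(out$report$column, c("mostly_missing", "constant"))
  expect_equal(out$report$rule[out$report$column == "mostly_missing"],
               "missingness")
  expect_equal(out$report$rule[out$report$column == "constant"],
               "zero_variance")
  g <- out$table$values[, "gap"]
  expect_equal(mean(g), 0, tolerance = 1e-9)
  expect_equal(sd(g), 1, tolerance = 1e-9)
  # the missing entry was imputed with the fit-subset median before scaling
  med <- median(V[, "gap"], na.rm = TRUE)
  imput <- V[, "gap"]; imput[is.na(imput)] <- med
  expect_equal(unname(g), unname((imput - mean(imput)) / sd(imput)),
               tolerance = 1e-9)
})

test_that("cleaning is idempotent and fit statistics ignore held-out rows", {
  fx <- small_cohort_features()
  tab <- fx$table
  once <- clean_features(tab)
  twice <- clean_features(once$table)
  expect_equal(twice$table$values, once$table$values, tolerance = 1e-8)
  expect_equal(nrow(twice$report), 0)

  # mutation guard: perturbing a held-out row leaves fit statistics intact
  fit_rows <- 1:10
  s1 <- kinectome:::fit_clean_stats(tab$values, fit_rows)
  V2 <- tab$values
  V2[14, ] <- V2[14, ] * 100 + 5
  s2 <- kinectome:::fit_clean_stats(V2, fit_rows)
  expect_identical(s1, s2)
})
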