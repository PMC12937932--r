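test_that("generation is deterministic for a fixed specification", {
  spec <- cohort_spec(n_group_a = 3, n_group_b = 3, duration = 3, seed = 9)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$recordings[[5]]$series, b$recordings[[5]]$series)
  c2 <- generate_cohort(cohort_spec(n_group_a = 3, n_group_b = 3,
                                    duration = 3, seed = 10))
  expect_false(identical(a$recordings[[1]]$series[[1]],
                         c2$recordings[[1]]$series[[1]]))
})

test_that("invalid cohort specifications are rejected", {
  expect_error(cohort_spec(n_group_a = 0), ">= 1")
  expect_error(cohort_spec(fs = 15), "cutoff")
  expect_error(cohort_spec(duration = 1, fs = 100), "256")
  expect_error(effect_spec(distal_speed_scale = -1), "nonnegative")
  expect_error(effect_spec(interlimb_decoupling = 2), "\\[0, 1\\]")
})

test_that("clinical scores are monotone in severity and perfectly rank-correlated without noise", {
  sev <- seq(-1.4, 1.4, length.out = 30)
  eff0 <- effect_spec(severity_noise_sd = 0)
  scores <- generate_clinical_scores(sev, eff0)
  for (col in names(scores)) {
    expect_false(is.unsorted(scores[[col]]), info = col)
  }
  expect_equal(cor(sev, scores$mds_updrs_total, method = "spearman"), 1)
  expect_true(all(scores$hy_stage >= 0 & scores$hy_stage <= 5))
  expect_true(all(as.matrix(scores) >= 0))
})

test_that("clinical score correlation attenuates with noise", {
  set.seed(31)
  sev <- rnorm(50)
  rho_of <- function(nsd) {
    sc <- generate_clinical_scores(sev, effect_spec(severity_noise_sd = nsd))
    # brute-force Spearman: Pearson correlation of midranks
    r1 <- rank(sev); r2 <- rank(sc$mds_updrs_total)
    sum((r1 - mean(r1)) * (r2 - mean(r2))) /
      sqrt(sum((r1 - mean(r1))^2) * sum((r2 - mean(r2))^2))
  }
  expect_gt(rho_of(0.05), 0.95)
  expect_lt(abs(rho_of(25)), 0.5)
})

test_that("each effect field moves its targeted feature family in the documented direction", {
  tpl <- kinectome:::segment_template()
  prox <- tpl$segment[tpl$proximal]
  distal <- tpl$segment[tpl$distal]
  al_arms <- c("Right Hand", "Left Hand", "Right Forearm", "Left Forearm")
  al_legs <- c("Right Upper Leg", "Left Upper Leg", "Right Lower Leg",
               "Left Lower Leg")
  delta <- function(eff, what, seeds, dur) {
    vapply(seeds, function(sd) {
      coh <- generate_cohort(cohort_spec(n_group_a = 4, n_group_b = 4,
                                         duration = dur, effect = eff,
                                         seed = sd))
      grp <- coh$metadata$group
      kin <- lapply(coh$recordings, kinematic_features)
      val <- switch(what,
        vel_distal = vapply(kin, function(k) {
          mean(k$features$vel_iqr[k$features$segment %in% distal])
        }, 0),
        pos_all = vapply(kin, function(k) mean(k$features$pos_iqr), 0),
        a_prox = vapply(kin, function(k) {
          A <- build_network(k$magnitudes)$A
          mean(A[prox, prox][upper.tri(diag(length(prox)))])
        }, 0),
        a_armleg = vapply(kin, function(k) {
          mean(build_network(k$magnitudes)$A[al_arms, al_legs])
        }, 0)
      )
      mean(val[grp == "case"]) - mean(val[grp == "control"])
    }, 0)
  }
  # bradykinesia-like scaling: distal speed IQR goes down in cases
  d1 <- delta(effect_spec(0.5, 0, 0, 0), "vel_distal", 1:5, 4)
  expect_true(all(d1 < 0))
  # postural drift: position IQR goes up (study-length recordings)
  d2 <- delta(effect_spec(1, 0.008, 0, 0), "pos_all", 1:4, 15)
  expect_true(mean(d2 > 0) >= 0.75)
  # proximal coupling: trunk/head adjacency weights go up
  d3 <- delta(effect_spec(1, 0, 1, 0), "a_prox", 1:4, 6)
  expect_true(all(d3 > 0))
  # interlimb decoupling: arm-leg adjacency weights go down
  d4 <- delta(effect_spec(1, 0, 0, 0.8), "a_armleg", 1:4, 6)
  expect_true(all(d4 < 0))
})

test_that("null effects leave the groups exchangeable on kinematic features", {
  # permutation check on one seed: the observed group difference in mean
  # distal speed IQR is not extreme among label permutations
  coh <- generate_cohort(cohort_spec(n_group_a = 6, n_group_b = 6,
                                     duration = 4,
                                     effect = null_effects(), seed = 5))
  kin <- lapply(coh$recordings, kinematic_features)
  distal <- kinectome:::segment_template()
  distal <- distal$segment[distal$distal]
  v <- vapply(kin, function(k) {
    mean(k$features$vel_iqr[k$features$segment %in% distal])
  }, 0)
  grp <- coh$metadata$group == "case"
  obs <- abs(mean(v[grp]) - mean(v[!grp]))
  set.seed(77)
  perm <- replicate(500, {
    g <- sample(grp)
    abs(mean(v[g]) - mean(v[!g]))
  })
  expect_gt(mean(perm >= obs), 0.05)
})

test_that("metadata demographics differ by design while controls lack clinical scores", {
  fx <- small_cohort_features()
  meta <- fx$cohort$metadata
  expect_true(mean(meta$age[meta$group == "case"]) >
                mean(meta$age[meta$group == "control"]) - 30)
  expect_true(all(is.na(meta$mds_updrs_total[meta$group == "control"])))
  expect_true(all(is.finite(meta$mds_updrs_total[meta$group == "case"])))
})
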