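# Shared fixtures, generated in code and cached across test files within a
# run so expensive simulations happen once.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Small effect cohort with precomputed kinematics, networks and features.
small_cohort_features <- function() {
  cached("small_cohort_features", {
    coh <- generate_cohort(cohort_spec(n_group_a = 8, n_group_b = 8,
                                       duration = 5, seed = 42))
    kin <- lapply(coh$recordings, kinematic_features)
    nets <- lapply(kin, function(k) build_network(k$magnitudes))
    gms <- lapply(nets, metrics_across_thresholds)
    tab <- assemble_features(kin, nets, gms)
    list(cohort = coh, kin = kin, nets = nets, gms = gms, table = tab)
  })
}

# Tiny labelled toy matrix with one strongly separating feature.
toy_separable <- function(n_per_group = 20, p_noise = 8, seed = 7) {
  set.seed(seed)
  n <- 2 * n_per_group
  X <- matrix(rnorm(n * (p_noise + 1)), n)
  colnames(X) <- c("signal", paste0("noise", seq_len(p_noise)))
  y <- rep(c(1L, 0L), each = n_per_group)
  X[, "signal"] <- ifelse(y == 1, 2, -2) + rnorm(n, 0, 0.5)
  list(X = X, y = y)
}

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
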