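# Shared fixtures, built once per test file. Sizes are kept small; the
# acceptance tests use their own, larger, configurations.

fix_profiles <- function(n_probes = 600, n_disc = 120, seed = 1) {
  make_reference_profiles(n_probes, 3, n_disc, separation = 0.5, seed = seed)
}

fix_panel <- function(profiles = fix_profiles(), seed = 2) {
  ref <- simulate_reference_samples(profiles, n_per_type = 12, seed = seed)
  select_discriminating_sites(ref$beta, ref$celltype, per_type = 100)
}

# Dense grid search over the constrained simplex (step 0.01), the independent
# oracle for the proportion solver on 3-cell-type problems.
grid_search_proportions <- function(R, m, step = 0.01) {
  best <- NULL
  best_obj <- Inf
  for (p1 in seq(0, 1, step)) {
    for (p2 in seq(0, 1 - p1, step)) {
      p3 <- seq(0, 1 - p1 - p2, step)
      obj <- colSums((m - R %*% rbind(p1, p2, matrix(p3, 1)))^2)
      j <- which.min(obj)
      if (obj[j] < best_obj) {
        best_obj <- obj[j]
        best <- c(p1, p2, p3[j])
      }
    }
  }
  best
}

# Closed-form OLS oracle (QR-free, textbook normal equations).
ols_oracle <- function(X, y) {
  xtx <- solve(t(X) %*% X)
  cf <- xtx %*% t(X) %*% y
  res <- y - X %*% cf
  sigma2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(coef = drop(cf), se = sqrt(diag(xtx) * sigma2))
}
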