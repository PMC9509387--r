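#' Matrix-level quality control and normalization
#'
#' Detection-p based sample/probe filtering, principal-component outlier
#' exclusion, between-sample quantile normalization, and the PC1 covariate
#' used downstream in the association models.
#'
#' @name qcnorm
NULL

#' Filter samples and probes by detection p-value failure fractions
#'
#' Removes samples in which more than `sample_frac` of probes have a
#' detection p-value above `detp_cut`, then (on the retained samples only)
#' removes probes failing in more than `probe_frac` of samples. Comparisons
#' are strict, so `sample_frac = 1` can never remove a sample. Samples are
#' filtered before probes, making the result deterministic.
#'
#' @param beta probe x sample beta matrix.
#' @param detp detection p-value matrix, axis-aligned with `beta`.
#' @param detp_cut detection p-value above which a measurement fails (0.05).
#' @param sample_frac maximum tolerated failing-probe fraction per sample (0.01).
#' @param probe_frac maximum tolerated failing-sample fraction per probe (0.01).
#' @return list with `beta` (filtered) and `report` (a `QCReport`: data frames
#'   `samples_removed` and `probes_removed` with failure fractions and reason).
#' @export
pfilter <- function(beta, detp, detp_cut = 0.05,
                    sample_frac = 0.01, probe_frac = 0.01) {
  stopifnot_aligned(beta, detp, "beta and detp")
  fail <- detp > detp_cut
  sfrac <- colMeans(fail)
  bad_s <- sfrac > sample_frac
  keep_s <- !bad_s
  if (!any(keep_s)) stop("all samples removed by detection-p filtering")
  pfrac <- rowMeans(fail[, keep_s, drop = FALSE])
  bad_p <- pfrac > probe_frac
  report <- structure(list(
    samples_removed = data.frame(
      sample_id = colnames(beta)[bad_s],
      fail_fraction = unname(sfrac[bad_s]),
      reason = rep(sprintf("> %g of probes with detection p > %g",
                           sample_frac, detp_cut), sum(bad_s)),
      stringsAsFactors = FALSE
    ),
    probes_removed = data.frame(
      probe_id = rownames(beta)[bad_p],
      fail_fraction = unname(pfrac[bad_p]),
      reason = rep(sprintf("> %g of samples with detection p > %g",
                           probe_frac, detp_cut), sum(bad_p)),
      stringsAsFactors = FALSE
    )
  ), class = "QCReport")
  list(beta = beta[!bad_p, keep_s, drop = FALSE], report = report)
}

# Sample scores on the first n_pcs principal components; missing values are
# mean-imputed per probe for the decomposition only.
pc_scores <- function(beta, n_pcs) {
  x <- beta
  if (anyNA(x)) {
    mu <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 1]]
  }
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  p$x[, seq_len(min(n_pcs, ncol(p$x))), drop = FALSE]
}

#' Remove principal-component outlier samples
#'
#' Computes sample scores on the first `n_pcs` principal components of the
#' centered beta matrix and removes samples whose robust z-score
#' (median/MAD) exceeds `z_cut` in absolute value on any PC. The procedure
#' iterates once (a second pass on the reduced matrix). As a guard, no more
#' than half of the samples are ever removed: if more are flagged, only the
#' most extreme half (by maximum |z|) are dropped.
#'
#' @param beta probe x sample beta matrix (>= 4 samples).
#' @param n_pcs number of leading PCs to screen (default 3).
#' @param z_cut robust z threshold (default 3).
#' @return list with `beta` (filtered) and `report` containing
#'   `samples_removed` and the per-sample per-PC `outlier_scores`.
#' @export
pc_outlier_removal <- function(beta, n_pcs = 3, z_cut = 3.0) {
  if (n_pcs < 1) stop("n_pcs must be >= 1")
  if (ncol(beta) < 4) stop("at least 4 samples required")
  removed <- character(0)
  scores_all <- NULL
  cur <- beta
  n0 <- ncol(beta)
  for (pass in 1:2) {
    sc <- pc_scores(cur, n_pcs)
    z <- apply(sc, 2, function(v) {
      s <- stats::mad(v)
      if (s < .Machine$double.eps) return(rep(0, length(v)))
      (v - stats::median(v)) / s
    })
    z <- matrix(z, nrow = nrow(sc), dimnames = dimnames(sc))
    if (pass == 1) scores_all <- z
    flag <- apply(abs(z) > z_cut, 1, any)
    if (!any(flag)) break
    cand <- colnames(cur)[flag]
    # 50% guard over the whole procedure
    budget <- floor(n0 / 2) - length(removed)
    if (length(cand) > budget) {
      mx <- apply(abs(z), 1, max)[flag]
      cand <- cand[order(mx, decreasing = TRUE)][seq_len(max(budget, 0))]
    }
    removed <- c(removed, cand)
    keep <- setdiff(colnames(cur), cand)
    if (length(keep) == 0) stop("all samples would be removed as PC outliers")
    cur <- cur[, keep, drop = FALSE]
  }
  report <- structure(list(
    samples_removed = data.frame(
      sample_id = removed,
      reason = rep(sprintf("|robust z| > %g on one of the first %d PCs",
                           z_cut, n_pcs), length(removed)),
      stringsAsFactors = FALSE
    ),
    outlier_scores = scores_all
  ), class = "QCReport")
  list(beta = cur, report = report)
}

#' Between-sample quantile normalization
#'
#' Forces every column's empirical distribution onto the mean of the sorted
#' columns; ties receive the mean of their would-be values; missing values
#' are left missing and excluded from rank computation.
#'
#' @param beta probe x sample matrix (>= 2 samples).
#' @return normalized matrix with identical dimnames.
#' @export
quantile_normalize <- function(beta) {
  if (ncol(beta) < 2) stop("at least 2 samples required")
  out <- limma::normalizeQuantiles(beta, ties = TRUE)
  dimnames(out) <- dimnames(beta)
  out
}

#' First principal-component covariate over the most variable probes
#'
#' Computes the PC1 score per sample on the `n_top_variable` most variable
#' probes (all probes if fewer), capturing residual structure for use as a
#' fixed-effect covariate. The sign is fixed so that the loading vector sums
#' to a non-negative value.
#'
#' @param beta probe x sample matrix (>= 3 samples).
#' @param n_top_variable number of most-variable probes used (default 10000).
#' @return named numeric vector of per-sample PC1 scores.
#' @export
compute_pc1 <- function(beta, n_top_variable = 10000) {
  if (ncol(beta) < 3) stop("at least 3 samples required")
  v <- apply(beta, 1, stats::var, na.rm = TRUE)
  keep <- order(v, decreasing = TRUE)[seq_len(min(n_top_variable, nrow(beta)))]
  x <- beta[keep, , drop = FALSE]
  if (anyNA(x)) {
    mu <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 1]]
  }
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  s <- p$x[, 1]
  if (sum(p$rotation[, 1]) < 0) s <- -s
  stats::setNames(s, colnames(beta))
}
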