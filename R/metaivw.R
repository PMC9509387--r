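#' Fixed-effects inverse-variance-weighted meta-analysis
#'
#' Pools per-probe effect estimates across cohort-level EWAS summary tables
#' with weights equal to the inverse squared standard errors, restricted to
#' probes present in a minimum number of cohorts, with Bonferroni control of
#' the pooled p-values.
#'
#' @name metaivw
NULL

check_cohorts <- function(cohorts) {
  if (!is.list(cohorts) || length(cohorts) < 1) stop("at least 1 cohort required")
  for (i in seq_along(cohorts)) {
    co <- cohorts[[i]]
    if (!all(c("probe_id", "effect", "se") %in% names(co))) {
      stop("each cohort needs probe_id, effect and se columns")
    }
    if (anyDuplicated(co$probe_id)) stop("duplicate probe ids within a cohort")
  }
  invisible(TRUE)
}

#' Probes testable in at least `min_cohorts` cohorts
#'
#' A probe contributes in a cohort when its effect and standard error are
#' present, finite, and the standard error is positive.
#'
#' @param cohorts named list of cohort summary data.frames
#'   (probe_id, effect, se, optionally n).
#' @param min_cohorts minimum number of contributing cohorts (default 2).
#' @return character vector of probe ids (sorted).
#' @export
harmonize_probes <- function(cohorts, min_cohorts = 2) {
  check_cohorts(cohorts)
  if (min_cohorts > length(cohorts)) {
    stop("min_cohorts exceeds the number of cohorts")
  }
  counts <- table(unlist(lapply(cohorts, function(co) {
    unique(co$probe_id[is.finite(co$effect) & is.finite(co$se) & co$se > 0])
  })))
  universe <- sort(names(counts)[counts >= min_cohorts])
  if (length(universe) == 0) stop("empty probe universe after harmonization")
  universe
}

#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' For each probe in the harmonized universe, the pooled effect is the
#' weighted mean of cohort effects with weights `w_i = 1/se_i^2`, the pooled
#' standard error is `(sum w_i)^(-1/2)`, and `z = pooled/pooled_se` is
#' referred to the standard normal (two-sided). Cochran's Q and I^2 are
#' reported for description but play no role in inference (fixed effects
#' only).
#'
#' @param cohorts named list of cohort summary data.frames.
#' @param min_cohorts minimum contributing cohorts per probe (default 2).
#' @return `MetaResult` data.frame: probe_id, pooled_effect, pooled_se, z, p,
#'   n_cohorts, cohort_ids (comma-separated), Q, I2; ordered by p then probe.
#' @export
ivw_meta <- function(cohorts, min_cohorts = 2) {
  universe <- harmonize_probes(cohorts, min_cohorts)
  if (is.null(names(cohorts))) {
    names(cohorts) <- sprintf("cohort%02d", seq_along(cohorts))
  }
  eff <- matrix(NA_real_, length(universe), length(cohorts),
                dimnames = list(universe, names(cohorts)))
  se <- eff
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    idx <- match(universe, co$probe_id)
    eff[, nm] <- co$effect[idx]
    se[, nm] <- co$se[idx]
  }
  contrib <- is.finite(eff) & is.finite(se) & se > 0
  eff[!contrib] <- NA
  se[!contrib] <- NA
  w <- 1 / se^2
  sw <- rowSums(w, na.rm = TRUE)
  pooled <- rowSums(w * eff, na.rm = TRUE) / sw
  pooled_se <- 1 / sqrt(sw)
  zv <- pooled / pooled_se
  nco <- rowSums(contrib)
  Q <- rowSums(w * (eff - pooled)^2, na.rm = TRUE)
  I2 <- ifelse(nco > 1 & Q > 0, pmax(0, (Q - (nco - 1)) / Q) * 100, 0)
  keep <- nco >= min_cohorts
  out <- data.frame(
    probe_id = universe[keep],
    pooled_effect = pooled[keep],
    pooled_se = pooled_se[keep],
    z = zv[keep],
    p = 2 * stats::pnorm(-abs(zv[keep])),
    n_cohorts = nco[keep],
    cohort_ids = apply(contrib[keep, , drop = FALSE], 1, function(r) {
      paste(names(cohorts)[r], collapse = ",")
    }),
    Q = Q[keep],
    I2 = I2[keep],
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$p, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("MetaResult", "data.frame")
  out
}

#' Bonferroni significance threshold
#'
#' Returns `alpha / n_tests` rounded to `sig_digits` significant digits for
#' reporting (halves away from zero, matching conventional printing); the
#' full-precision value is attached as the `exact` attribute and should be
#' used for thresholding.
#'
#' @param alpha family-wise error rate in (0,1).
#' @param n_tests number of tests (>= 1).
#' @param sig_digits significant digits for display (default 3).
#' @return displayed threshold with attribute `exact`.
#' @export
bonferroni_threshold <- function(alpha, n_tests, sig_digits = 3) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)")
  if (n_tests < 1) stop("n_tests must be >= 1")
  exact <- alpha / n_tests
  out <- signif_half_up(exact, sig_digits)
  attr(out, "exact") <- exact
  out
}
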