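#' Direction concordance between result sets and nuclei-fraction analyses
#'
#' Sign tests for consistency of effect direction between analyses,
#' hyper/hypomethylation enrichment, high-versus-low pathology group EWAS in
#' purified nuclei fractions, and bulk-versus-fraction effect-size
#' fold-change reports.
#'
#' @name concord
NULL

#' One-sided exact binomial sign test
#'
#' Probability of observing at least `k_concordant` agreements out of `n`
#' under a fair coin: `P(X >= k)`, `X ~ Binomial(n, 1/2)`. Full concordance
#' reduces to `0.5^n`.
#'
#' @param k_concordant number of concordant sites (0..n).
#' @param n number of sites compared (>= 1).
#' @return one-sided upper-tail p-value.
#' @export
sign_test <- function(k_concordant, n) {
  if (n < 1) stop("n must be >= 1")
  if (k_concordant < 0 || k_concordant > n) stop("k_concordant must be in 0..n")
  stats::pbinom(k_concordant - 1, n, 0.5, lower.tail = FALSE)
}

#' One-sided enrichment test for effect direction
#'
#' The same exact binomial computation as [sign_test()], applied to the count
#' of hypermethylated (or hypomethylated) sites among `n` significant sites;
#' exposed separately for report labeling.
#'
#' @param k_positive sites in the tested direction.
#' @param n total sites.
#' @return one-sided upper-tail p-value.
#' @export
direction_enrichment <- function(k_positive, n) {
  sign_test(k_positive, n)
}

#' High- versus low-pathology group EWAS in a nuclei fraction
#'
#' Per site, ordinary least squares of methylation on the binary group
#' indicator controlling for age, sex and batch; the effect is the
#' percentage-point high-minus-low difference. Sites with zero variance are
#' skipped and recorded.
#'
#' @param beta_fraction probe x sample beta matrix for one nuclei fraction.
#' @param labels data.frame with sample_id, group ("low"/"high"), age, sex,
#'   batch; at least 3 samples per group.
#' @param threshold significance threshold on p.
#' @return `EWASResult` data.frame: probe_id, effect, se, statistic, p_value,
#'   n_samples, model_label; ordered by p then probe id.
#' @export
high_low_group_ewas <- function(beta_fraction, labels, threshold = 9e-8) {
  idx <- match(colnames(beta_fraction), labels$sample_id)
  if (anyNA(idx)) stop("labels missing for some samples")
  labels <- labels[idx, , drop = FALSE]
  if (!all(c("low", "high") %in% labels$group)) stop("both groups must be nonempty")
  if (min(table(labels$group)) < 3) stop("at least 3 samples per group required")
  g <- as.integer(labels$group == "high")
  d <- data.frame(g = g, age = labels$age, sex = labels$sex, batch = labels$batch)
  # batch/sex may be constant in tiny studies; drop constant covariates
  covs <- c("age", "sex", "batch")
  covs <- covs[vapply(covs, function(cv) length(unique(d[[cv]])) > 1, logical(1))]
  X <- stats::model.matrix(
    stats::as.formula(paste(c("~ g", covs), collapse = " + ")), d)
  eng <- ols_engine(X)
  rows <- vector("list", nrow(beta_fraction))
  skipped <- character(0)
  for (i in seq_len(nrow(beta_fraction))) {
    y <- beta_fraction[i, ]
    if (!all(is.finite(y)) || stats::var(y) < .Machine$double.eps) {
      skipped <- c(skipped, rownames(beta_fraction)[i])
      next
    }
    f <- ols_fit_one(eng, y)
    stat <- f$coef["g"] / f$se["g"]
    rows[[i]] <- data.frame(
      probe_id = rownames(beta_fraction)[i],
      effect = unname(f$coef["g"]) * 100,
      se = unname(f$se["g"]) * 100,
      statistic = unname(stat),
      p_value = 2 * stats::pt(-abs(unname(stat)), eng$n - eng$p),
      n_samples = length(y),
      model_label = "high_vs_low",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  if (nrow(out) > 0) {
    out <- out[order(out$p_value, out$probe_id), , drop = FALSE]
    rownames(out) <- NULL
    out$significant <- out$p_value < threshold
  }
  attr(out, "skipped") <- skipped
  class(out) <- c("EWASResult", "data.frame")
  out
}

#' Direction-concordance and effect-amplification report
#'
#' Compares effect directions between a reference result set (for example a
#' bulk-cortex meta-analysis) and a second result set (for example a
#' purified-fraction group EWAS) over `site_set`. Concordance is agreement
#' of effect sign; its p-value is the one-sided sign test. The mean
#' fold-change is the mean over sites of |effect_b| / |effect_a|, with sites
#' whose reference effect is exactly zero excluded (and counted); a
#' ratio-of-means alternative is available.
#'
#' @param reference_results,fraction_results data.frames with probe_id and
#'   effect columns.
#' @param site_set probe ids to compare (the intersection with both result
#'   sets is used and reported).
#' @param ratio_of_means if TRUE, report |mean-ratio| of absolute effects
#'   instead of the mean of per-site ratios.
#' @return A `ConcordanceReport` list: n_sites, n_concordant,
#'   fraction_concordant, sign_p, mean_fold_change, n_zero_reference,
#'   per_site table.
#' @export
concordance_report <- function(reference_results, fraction_results, site_set,
                               ratio_of_means = FALSE) {
  a <- reference_results[match(site_set, reference_results$probe_id), ]
  b <- fraction_results[match(site_set, fraction_results$probe_id), ]
  ok <- !is.na(a$probe_id) & !is.na(b$probe_id) &
    is.finite(a$effect) & is.finite(b$effect)
  if (!any(ok)) stop("empty intersection between result sets and site_set")
  a <- a[ok, ]
  b <- b[ok, ]
  n <- nrow(a)
  concordant <- sign(a$effect) == sign(b$effect)
  k <- sum(concordant)
  nz <- a$effect != 0
  fold <- if (ratio_of_means) {
    mean(abs(b$effect[nz])) / mean(abs(a$effect[nz]))
  } else {
    mean(abs(b$effect[nz]) / abs(a$effect[nz]))
  }
  structure(list(
    n_sites = n,
    n_concordant = k,
    fraction_concordant = k / n,
    sign_p = sign_test(k, n),
    mean_fold_change = fold,
    n_zero_reference = sum(!nz),
    per_site = data.frame(
      probe_id = a$probe_id,
      effect_reference = a$effect,
      effect_fraction = b$effect,
      concordant = concordant,
      fold_change = ifelse(nz, abs(b$effect) / abs(a$effect), NA_real_),
      stringsAsFactors = FALSE
    )
  ), class = "ConcordanceReport")
}

#' @export
print.ConcordanceReport <- function(x, ...) {
  cat(sprintf(
    "Concordance over %d sites: %d concordant (%.1f%%), sign-test p = %.3g\n",
    x$n_sites, x$n_concordant, 100 * x$fraction_concordant, x$sign_p))
  cat(sprintf("Mean fold-change in |effect| = %.3g (%d zero-reference sites excluded)\n",
              x$mean_fold_change, x$n_zero_reference))
  invisible(x)
}
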