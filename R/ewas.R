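#' Per-probe association of methylation with neuropathology
#'
#' Cross-cortex linear mixed models with a donor random intercept, joint
#' multi-measure likelihood-ratio tests, region-interaction tests, per-region
#' ordinary least squares, and cell-proportion-versus-pathology regressions.
#' Methylation is analyzed on the beta (proportion) scale and coefficients
#' are reported as percentage points of methylation per unit predictor.
#'
#' @name ewas
NULL

prop_column <- function(celltype) {
  paste0("prop_", gsub("[^A-Za-z0-9]", "", celltype))
}

#' Attach deconvolved proportions and PC1 to a phenotype table
#'
#' Adds `prop_*` columns (percent-free, on the 0-1 scale) and a `pc1` column
#' aligned by sample_id, ready for use as model covariates.
#'
#' @param pheno phenotype data.frame with a sample_id column.
#' @param proportions `CellProportions` (or data.frame with sample_id and one
#'   column per cell type); optional.
#' @param pc1 named vector of PC1 scores (names = sample ids); optional.
#' @return phenotype data.frame with added columns.
#' @export
attach_covariates <- function(pheno, proportions = NULL, pc1 = NULL) {
  out <- pheno
  if (!is.null(proportions)) {
    idx <- match(out$sample_id, proportions$sample_id)
    if (anyNA(idx)) stop("proportions missing for some samples")
    for (ct in setdiff(names(proportions), c("sample_id", "residual_norm"))) {
      out[[prop_column(ct)]] <- proportions[[ct]][idx]
    }
  }
  if (!is.null(pc1)) {
    idx <- match(out$sample_id, names(pc1))
    if (anyNA(idx)) stop("pc1 scores missing for some samples")
    out$pc1 <- unname(pc1[idx])
  }
  out
}

#' Specify an association model
#'
#' @param predictors character vector of neuropathology predictors (among
#'   braak_nft, cerad, thal, braak_lb, tdp43). May be empty only for the
#'   degenerate joint test.
#' @param covariates fixed-effect covariate column names. At most two of the
#'   three cell-proportion covariates may be included (the third is nearly
#'   collinear through the sum constraint).
#' @param random_intercept include a donor random intercept.
#' @param interaction_with_region add predictor-by-region interaction terms
#'   (plus a region main effect).
#' @return a `ModelSpec` list.
#' @export
ewas_model_spec <- function(predictors = c("braak_nft", "cerad", "thal"),
                            covariates = c("age", "sex", "batch", "pc1",
                                           "prop_NeuN", "prop_DN"),
                            random_intercept = TRUE,
                            interaction_with_region = FALSE) {
  allowed <- c("braak_nft", "cerad", "thal", "braak_lb", "tdp43")
  if (length(predictors) > 0 && !all(predictors %in% allowed)) {
    stop("predictors must be among: ", paste(allowed, collapse = ", "))
  }
  props <- intersect(covariates, c("prop_NeuN", "prop_SOX10", "prop_DN"))
  if (length(props) > 2) {
    stop("include at most two of the three cell-proportion covariates")
  }
  structure(list(
    predictors = predictors,
    covariates = covariates,
    random_intercept = isTRUE(random_intercept),
    interaction_with_region = isTRUE(interaction_with_region)
  ), class = "ModelSpec")
}

build_fixed_formula <- function(spec, include_predictors = TRUE) {
  terms <- character(0)
  if (include_predictors && length(spec$predictors) > 0) {
    if (spec$interaction_with_region) {
      terms <- c(terms, paste0(spec$predictors, " * region"))
    } else {
      terms <- c(terms, spec$predictors)
    }
  } else if (spec$interaction_with_region) {
    terms <- c(terms, "region")
  }
  terms <- c(terms, spec$covariates)
  if (length(terms) == 0) terms <- "1"
  stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
}

model_columns <- function(spec) {
  cols <- unique(c(spec$predictors, spec$covariates))
  if (spec$interaction_with_region) cols <- c(cols, "region")
  if (spec$random_intercept) cols <- c(cols, "donor_id")
  cols
}

# Wald coefficient table from an lmer or lm fit, on the percentage-point scale.
wald_table <- function(fit) {
  co <- if (inherits(fit, "merMod")) {
    as.data.frame(stats::coef(summary(fit)))[, 1:3]
  } else {
    as.data.frame(summary(fit)$coefficients)[, 1:3]
  }
  names(co) <- c("effect", "se", "statistic")
  data.frame(
    term = rownames(co),
    effect = co$effect * 100,
    se = co$se * 100,
    statistic = co$statistic,
    p_value = 2 * stats::pnorm(-abs(co$statistic)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Fit the per-site linear mixed model
#'
#' Fits methylation (beta scale) against the model's predictors and
#' covariates with a donor random intercept (REML), reporting Wald tests per
#' coefficient with effects in percentage points per unit predictor. When
#' the random-effect variance estimate hits the zero boundary or the fit
#' fails to converge, the model falls back to ordinary least squares and the
#' result is flagged.
#'
#' @param y numeric methylation vector on [0,1], aligned with `pheno` rows.
#' @param pheno phenotype data.frame (with covariates attached).
#' @param spec a `ModelSpec`.
#' @return data.frame of per-coefficient (term, effect, se, statistic,
#'   p_value) with attributes `n_samples`, `n_donors`, `fallback`,
#'   `skipped`/`skip_reason`; or a skip record when y has zero variance.
#' @export
fit_site_lmm <- function(y, pheno, spec) {
  stopifnot(inherits(spec, "ModelSpec"), length(y) == nrow(pheno))
  if (length(spec$predictors) == 0) stop("spec must contain at least one predictor")
  cols <- model_columns(spec)
  dat <- pheno[, unique(c("donor_id", cols)), drop = FALSE]
  dat$y <- y
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n_donors <- length(unique(dat$donor_id))
  if (n_donors < 10) stop("at least 10 donors required")
  if (stats::var(dat$y) < .Machine$double.eps) {
    out <- data.frame(term = character(0), effect = numeric(0), se = numeric(0),
                      statistic = numeric(0), p_value = numeric(0))
    attr(out, "skipped") <- TRUE
    attr(out, "skip_reason") <- "zero variance"
    return(out)
  }
  ff <- build_fixed_formula(spec)
  fallback <- FALSE
  fit <- NULL
  if (spec$random_intercept && any(duplicated(dat$donor_id))) {
    lf <- stats::as.formula(paste(c(deparse(ff), "+ (1 | donor_id)"), collapse = " "))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(lf, data = dat, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE)))),
      error = function(e) NULL)
    if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
      fallback <- TRUE
      fit <- NULL
    }
  } else {
    fallback <- spec$random_intercept
  }
  if (is.null(fit)) fit <- stats::lm(ff, data = dat)
  out <- wald_table(fit)
  attr(out, "n_samples") <- nrow(dat)
  attr(out, "n_donors") <- n_donors
  attr(out, "fallback") <- fallback
  out
}

# Gaussian ML log-likelihood of an OLS fit from its residual sum of squares.
ols_ml_loglik <- function(rss, n) {
  -n / 2 * (log(2 * pi) + log(rss / n) + 1)
}

#' Joint likelihood-ratio test of several neuropathology measures
#'
#' Compares the full mixed model containing all predictors in `spec` to the
#' null model without them, both fit by maximum likelihood (not REML), and
#' refers twice the log-likelihood difference to a chi-square with one
#' degree of freedom per predictor. If the random-intercept fit is singular
#' or fails, both models are refit by ordinary least squares (the Gaussian
#' ML likelihood ratio) and the result is flagged.
#'
#' @param y methylation vector on [0,1].
#' @param pheno phenotype data.frame.
#' @param spec a `ModelSpec`; an empty predictor set yields statistic 0, p 1.
#' @return named list with `chi2`, `df`, `p_value`, `fallback`.
#' @export
joint_pathology_test <- function(y, pheno, spec) {
  stopifnot(inherits(spec, "ModelSpec"), length(y) == nrow(pheno))
  df <- length(spec$predictors)
  if (df == 0) return(list(chi2 = 0, df = 0, p_value = 1, fallback = FALSE))
  cols <- model_columns(spec)
  dat <- pheno[, unique(c("donor_id", cols)), drop = FALSE]
  dat$y <- y
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  if (stats::var(dat$y) < .Machine$double.eps) {
    stop("zero variance of y")
  }
  ff_full <- build_fixed_formula(spec, include_predictors = TRUE)
  ff_null <- build_fixed_formula(spec, include_predictors = FALSE)
  fallback <- FALSE
  ll <- NULL
  if (spec$random_intercept && any(duplicated(dat$donor_id))) {
    fits <- lapply(list(ff_full, ff_null), function(f) {
      lf <- stats::as.formula(paste(c(deparse(f), "+ (1 | donor_id)"), collapse = " "))
      tryCatch(
        suppressMessages(suppressWarnings(
          lme4::lmer(lf, data = dat, REML = FALSE,
                     control = lme4::lmerControl(calc.derivs = FALSE)))),
        error = function(e) NULL)
    })
    if (!any(vapply(fits, is.null, logical(1))) &&
        !any(vapply(fits, lme4::isSingular, logical(1), tol = 1e-5))) {
      ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
    }
  }
  if (is.null(ll)) {
    fallback <- TRUE
    n <- nrow(dat)
    ll <- vapply(list(ff_full, ff_null), function(f) {
      fit <- stats::lm(f, data = dat)
      ols_ml_loglik(sum(stats::resid(fit)^2), n)
    }, numeric(1))
  }
  chi2 <- max(0, 2 * (ll[1] - ll[2]))
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       fallback = fallback)
}

# Precomputed OLS engine: shared design across probes.
ols_engine <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) stop("design matrix is rank deficient")
  xtx_inv <- chol2inv(qr.R(qrx))
  list(qr = qrx, se_base = stats::setNames(sqrt(diag(xtx_inv)), colnames(X)),
       p = ncol(X), n = nrow(X))
}

ols_fit_one <- function(eng, y) {
  cf <- qr.coef(eng$qr, y)
  res <- y - qr.fitted(eng$qr, y)
  rss <- sum(res^2)
  sigma2 <- rss / (eng$n - eng$p)
  list(coef = cf, se = eng$se_base * sqrt(sigma2), rss = rss)
}

#' Run an EWAS across all probes
#'
#' Applies the per-site model to every probe. With `method = "wald"` the
#' coefficient of the first predictor in `spec` is reported; with
#' `method = "joint"` the likelihood-ratio test of all predictors is
#' reported (effect and se are NA). Probes whose fits fail are recorded and
#' skipped; the run continues. For speed, a single fitted model is reused
#' across probes via `lme4::refit` where the retained samples coincide.
#'
#' @param beta probe x sample matrix.
#' @param pheno phenotype table with covariates attached; samples with
#'   missing covariates are dropped globally, missing betas probe-wise.
#' @param spec a `ModelSpec`.
#' @param method "wald" or "joint".
#' @param threshold significance threshold on p (default 9e-8, the
#'   experiment-wide cutoff for EPIC-scale EWAS).
#' @return `EWASResult` data.frame ordered by p then probe_id: probe_id,
#'   effect, se, statistic, p_value, n_samples, n_donors, model_label,
#'   significant, fallback; attribute `significant` holds the significant
#'   probe ids, `skipped` the skip records.
#' @export
run_ewas <- function(beta, pheno, spec, method = c("wald", "joint"),
                     threshold = 9e-8) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "ModelSpec"))
  idx <- match(colnames(beta), pheno$sample_id)
  if (anyNA(idx)) stop("pheno missing for some samples")
  pheno <- pheno[idx, , drop = FALSE]
  cols <- model_columns(spec)
  cc <- stats::complete.cases(pheno[, unique(c("donor_id", cols)), drop = FALSE])
  pheno <- pheno[cc, , drop = FALSE]
  beta <- beta[, cc, drop = FALSE]
  if (length(spec$predictors) == 0) stop("spec must contain predictors")
  label <- sprintf("%s[%s]", method, paste(spec$predictors, collapse = "+"))

  n_donors <- length(unique(pheno$donor_id))
  use_lmm <- spec$random_intercept && any(duplicated(pheno$donor_id))
  ff_full <- build_fixed_formula(spec, TRUE)
  ff_null <- build_fixed_formula(spec, FALSE)
  dat <- pheno
  dat$y <- beta[1, ]

  # templates for the fast path (complete y)
  tmpl <- NULL
  if (use_lmm) {
    make_tmpl <- function(f, reml) {
      lf <- stats::as.formula(paste(c(deparse(f), "+ (1 | donor_id)"), collapse = " "))
      suppressMessages(suppressWarnings(
        lme4::lmer(lf, data = dat, REML = reml,
                   control = lme4::lmerControl(calc.derivs = FALSE))))
    }
    tmpl <- if (method == "wald") {
      list(full = make_tmpl(ff_full, TRUE))
    } else {
      list(full = make_tmpl(ff_full, FALSE), null = make_tmpl(ff_null, FALSE))
    }
  }
  X_full <- stats::model.matrix(ff_full, dat)
  X_null <- stats::model.matrix(ff_null, dat)
  eng_full <- ols_engine(X_full)
  eng_null <- ols_engine(X_null)
  coef_name <- spec$predictors[1]

  rows <- vector("list", nrow(beta))
  skipped <- list()
  for (i in seq_len(nrow(beta))) {
    y <- beta[i, ]
    ok <- is.finite(y)
    if (sum(ok) < ncol(X_full) + 2 || stats::var(y[ok]) < .Machine$double.eps) {
      skipped[[rownames(beta)[i]]] <- "zero variance or too few observations"
      next
    }
    complete <- all(ok)
    res <- tryCatch({
      if (method == "wald") {
        fit <- NULL
        fb <- !use_lmm
        if (use_lmm && complete) {
          fit <- tryCatch(suppressMessages(suppressWarnings(
            lme4::refit(tmpl$full, newresp = y))), error = function(e) NULL)
          if (is.null(fit) || lme4::isSingular(fit, tol = 1e-5)) {
            fit <- NULL
            fb <- TRUE
          }
        } else if (use_lmm) {
          tb <- fit_site_lmm(y, pheno, spec)
          fit <- NULL
          fb <- attr(tb, "fallback")
          row <- tb[tb$term == coef_name, ]
          res0 <- c(row$effect, row$se, row$statistic, row$p_value)
        }
        if (use_lmm && complete && !is.null(fit)) {
          co <- stats::coef(summary(fit))[coef_name, ]
          res0 <- c(co[1] * 100, co[2] * 100, co[3],
                    2 * stats::pnorm(-abs(co[3])))
        } else if (fb && (complete || !use_lmm)) {
          yy <- y
          eng <- eng_full
          if (!complete) {
            eng <- ols_engine(X_full[ok, , drop = FALSE])
            yy <- y[ok]
          }
          f <- ols_fit_one(eng, yy)
          stat <- f$coef[coef_name] / f$se[coef_name]
          res0 <- c(f$coef[coef_name] * 100, f$se[coef_name] * 100, stat,
                    2 * stats::pnorm(-abs(stat)))
        }
        list(effect = res0[1], se = res0[2], statistic = res0[3],
             p_value = res0[4], fallback = fb)
      } else {
        fb <- !use_lmm
        st <- NULL
        if (use_lmm && complete) {
          f1 <- tryCatch(suppressMessages(suppressWarnings(
            lme4::refit(tmpl$full, newresp = y))), error = function(e) NULL)
          f0 <- tryCatch(suppressMessages(suppressWarnings(
            lme4::refit(tmpl$null, newresp = y))), error = function(e) NULL)
          if (!is.null(f1) && !is.null(f0) &&
              !lme4::isSingular(f1, tol = 1e-5) &&
              !lme4::isSingular(f0, tol = 1e-5)) {
            st <- 2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0)))
          }
        }
        if (is.null(st)) {
          fb <- TRUE
          yy <- y[ok]
          e1 <- if (complete) eng_full else ols_engine(X_full[ok, , drop = FALSE])
          e0 <- if (complete) eng_null else ols_engine(X_null[ok, , drop = FALSE])
          r1 <- ols_fit_one(e1, yy)$rss
          r0 <- ols_fit_one(e0, yy)$rss
          st <- sum(ok) * log(r0 / r1)
        }
        st <- max(0, st)
        list(effect = NA_real_, se = NA_real_, statistic = st,
             p_value = stats::pchisq(st, length(spec$predictors), lower.tail = FALSE),
             fallback = fb)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      skipped[[rownames(beta)[i]]] <- "fit failed"
      next
    }
    rows[[i]] <- data.frame(
      probe_id = rownames(beta)[i], effect = unname(res$effect),
      se = unname(res$se), statistic = unname(res$statistic),
      p_value = unname(res$p_value), n_samples = sum(ok),
      n_donors = n_donors, model_label = label,
      fallback = res$fallback, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  if (nrow(out) > 0) {
    out <- out[order(out$p_value, out$probe_id), , drop = FALSE]
    rownames(out) <- NULL
    out$significant <- out$p_value < threshold
  }
  attr(out, "significant") <- out$probe_id[out$significant]
  attr(out, "skipped") <- skipped
  attr(out, "threshold") <- threshold
  class(out) <- c("EWASResult", "data.frame")
  out
}

#' Test for region-specific neuropathology effects
#'
#' Fits the mixed model with a predictor-by-region interaction (plus a region
#' main effect) and reports the Wald test of the interaction coefficient.
#'
#' @param y methylation vector on [0,1].
#' @param pheno phenotype table; both regions must be present.
#' @param spec a `ModelSpec` with a single predictor.
#' @return list with `effect_interaction` (percentage points per unit, region
#'   contrast), `se`, `statistic`, `p_value`.
#' @export
region_interaction_test <- function(y, pheno, spec) {
  if (length(unique(pheno$region)) < 2) stop("both regions required")
  if (length(spec$predictors) != 1) stop("spec must contain exactly one predictor")
  ispec <- spec
  ispec$interaction_with_region <- TRUE
  tb <- fit_site_lmm(y, pheno, ispec)
  if (isTRUE(attr(tb, "skipped"))) stop("zero variance of y")
  row <- tb[grepl(paste0("^", spec$predictors, ":region"), tb$term), ]
  if (nrow(row) != 1) stop("interaction coefficient not found")
  list(effect_interaction = row$effect, se = row$se,
       statistic = row$statistic, p_value = row$p_value,
       fallback = attr(tb, "fallback"))
}

#' Single-region EWAS by ordinary least squares
#'
#' Runs the per-probe model within one brain region (one sample per donor,
#' hence no random effect), with the same covariates as the cross-region
#' model.
#'
#' @param beta probe x sample matrix.
#' @param pheno phenotype table.
#' @param region "DLPFC" or "OCC".
#' @param spec a `ModelSpec`.
#' @param method,threshold as in [run_ewas()].
#' @return `EWASResult` data.frame (see [run_ewas()]).
#' @export
per_region_ewas <- function(beta, pheno, region, spec,
                            method = "wald", threshold = 9e-8) {
  keep <- pheno$region == region
  if (!any(keep)) stop("no samples in region ", region)
  spec2 <- spec
  spec2$random_intercept <- FALSE
  run_ewas(beta[, pheno$sample_id[keep], drop = FALSE],
           pheno[keep, , drop = FALSE], spec2,
           method = method, threshold = threshold)
}

#' Regress cell proportions against a neuropathology measure per region
#'
#' For each region and cell type, fits the linear regression of the
#' proportion (percentage points) on the measure, controlling for age and
#' sex, and flags significance at the Bonferroni level alpha / n_tests
#' (default 0.05/6: three cell types in two regions).
#'
#' @param proportions `CellProportions` (or data.frame with sample_id and one
#'   column per cell type).
#' @param pheno phenotype table.
#' @param measure neuropathology column (default braak_nft).
#' @param regions regions to test.
#' @param alpha family-wise error rate (default 0.05).
#' @param n_tests Bonferroni divisor (default: regions x cell types).
#' @return data.frame with region, celltype, effect (pp per unit), se,
#'   statistic, p_value, significant.
#' @export
proportions_vs_pathology <- function(proportions, pheno,
                                     measure = "braak_nft",
                                     regions = c("DLPFC", "OCC"),
                                     alpha = 0.05, n_tests = NULL) {
  cts <- setdiff(names(proportions), c("sample_id", "residual_norm"))
  if (is.null(n_tests)) n_tests <- length(regions) * length(cts)
  idx <- match(pheno$sample_id, proportions$sample_id)
  if (anyNA(idx)) stop("proportions and pheno are not aligned")
  cut <- alpha / n_tests
  rows <- list()
  for (rg in regions) {
    keep <- pheno$region == rg
    for (ct in cts) {
      d <- data.frame(p = proportions[[ct]][idx][keep] * 100,
                      m = pheno[[measure]][keep],
                      age = pheno$age[keep], sex = pheno$sex[keep])
      d <- d[stats::complete.cases(d), ]
      fit <- stats::lm(p ~ m + age + sex, data = d)
      co <- summary(fit)$coefficients["m", ]
      rows[[paste(rg, ct)]] <- data.frame(
        region = rg, celltype = ct, effect = co[1], se = co[2],
        statistic = co[3], p_value = co[4], significant = co[4] < cut,
        stringsAsFactors = FALSE, row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "bonferroni_cutoff") <- cut
  out
}
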