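#' Empirical-null bias and inflation adjustment
#'
#' Epigenome-wide association statistics are frequently biased (nonzero
#' center) and inflated (null scale above 1) by unmodeled structure. The
#' empirical null is estimated from the z-score vector as the central
#' component of a three-component Gaussian mixture (null plus one left and
#' one right signal component) fit by expectation-maximization, and
#' statistics are rescaled by `(z - bias) / inflation`.
#'
#' @name nulladjust
NULL

gauss_mix_loglik <- function(z, w, mu, sd) {
  dens <- vapply(1:3, function(k) w[k] * stats::dnorm(z, mu[k], sd[k]),
                 numeric(length(z)))
  sum(log(pmax(rowSums(dens), 1e-300)))
}

#' Estimate the empirical null from a vector of z-scores
#'
#' With `method = "mixture"`, fits a three-component Gaussian mixture by
#' maximum a posteriori EM, initialized from the median and MAD: a central
#' null component and two signal components. Three guards keep the central
#' component identifiable when the data are (nearly) all null: the signal
#' means stay at least `mean_gap` z-units from the null mean, the signal SDs
#' are never smaller than the null SD, and a weakly informative Dirichlet
#' prior on the mixing weights (prior counts `null_prior_frac * n` on the
#' null component) encodes the assumption that most probes are null. The
#' central component's mean and SD are returned as bias and inflation. With
#' `method = "robust"`, the median and the 1.4826-consistent MAD are
#' returned directly. If EM has not converged after `max_iter` iterations,
#' the robust estimate is returned with a warning flag.
#'
#' @param z numeric vector of at least 100 finite z-scores.
#' @param method "mixture" or "robust".
#' @param max_iter maximum EM iterations.
#' @param tol relative objective convergence tolerance.
#' @param mean_gap minimum distance of signal means from the null mean.
#' @param null_prior_frac Dirichlet prior counts for the null weight, as a
#'   fraction of the number of z-scores.
#' @param seed accepted for interface stability; the EM point estimate is
#'   deterministic given the data.
#' @return A `NullParams` list: `bias`, `inflation`, `null_weight`,
#'   `method`, `converged`, `n_iter`, and the per-iteration penalized
#'   `objective_trace` (mixture method only).
#' @export
estimate_empirical_null <- function(z, method = c("mixture", "robust"),
                                    max_iter = 1000, tol = 1e-8,
                                    mean_gap = 1, null_prior_frac = 0.05,
                                    seed = NULL) {
  method <- match.arg(method)
  z <- z[is.finite(z)]
  if (length(z) < 100) stop("at least 100 finite z-scores required")
  med <- stats::median(z)
  scale <- stats::mad(z)
  robust <- structure(list(bias = med, inflation = scale, null_weight = 1,
                           method = "robust", converged = TRUE, n_iter = 0L),
                      class = "NullParams")
  if (method == "robust") return(robust)

  n <- length(z)
  prior <- null_prior_frac * n * c(1, 0, 0)
  mu <- c(med, med - 3 * scale, med + 3 * scale)
  sd <- c(scale, 2 * scale, 2 * scale)
  w <- c(0.9, 0.05, 0.05)
  objective <- function(w, mu, sd) {
    gauss_mix_loglik(z, w, mu, sd) + sum(prior * log(w))
  }
  obj_trace <- numeric(0)
  obj_old <- -Inf
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # E step
    dens <- vapply(1:3, function(k) w[k] * stats::dnorm(z, mu[k], sd[k]),
                   numeric(n))
    tot <- pmax(rowSums(dens), 1e-300)
    r <- dens / tot
    # M step (MAP for the weights)
    nk <- colSums(r)
    w <- (nk + prior) / (n + sum(prior))
    for (k in 1:3) {
      if (nk[k] < 1e-8) next
      mu[k] <- sum(r[, k] * z) / nk[k]
      sd[k] <- sqrt(sum(r[, k] * (z - mu[k])^2) / nk[k])
    }
    # identifiability guards
    mu[2] <- min(mu[2], mu[1] - mean_gap)
    mu[3] <- max(mu[3], mu[1] + mean_gap)
    sd <- pmax(sd, 1e-3)
    sd[2] <- max(sd[2], sd[1])
    sd[3] <- max(sd[3], sd[1])
    obj <- objective(w, mu, sd)
    obj_trace <- c(obj_trace, obj)
    if (is.finite(obj_old) && abs(obj - obj_old) < tol * (abs(obj_old) + 1)) {
      converged <- TRUE
      break
    }
    obj_old <- obj
  }
  if (!converged) {
    warning("EM did not converge; returning robust estimate")
    robust$converged <- FALSE
    robust$n_iter <- it
    return(robust)
  }
  structure(list(bias = mu[1], inflation = sd[1], null_weight = w[1],
                 method = "mixture", converged = TRUE, n_iter = it,
                 objective_trace = obj_trace),
            class = "NullParams")
}

#' Rescale association statistics by the empirical null
#'
#' Computes `z_adj = (z - bias) / inflation`, two-sided normal p-values of
#' the adjusted z, and a propagated standard error `se_adj = effect / z_adj`
#' (missing where `z_adj` is 0). Effects are left unchanged so that reported
#' effect sizes keep their percentage-point meaning; original columns are
#' retained.
#'
#' @param ewas_table data.frame with a `statistic` (z) column, or `effect`
#'   and `se` columns from which z = effect/se is derived.
#' @param params `NullParams` from [estimate_empirical_null()].
#' @return the input with added columns `z_adj`, `p_adj`, `se_adj`.
#' @export
adjust_statistics <- function(ewas_table, params) {
  stopifnot(inherits(params, "NullParams"))
  if (params$inflation <= 0) stop("inflation must be positive")
  z <- if (!is.null(ewas_table$statistic)) {
    ewas_table$statistic
  } else {
    ewas_table$effect / ewas_table$se
  }
  z_adj <- (z - params$bias) / params$inflation
  out <- ewas_table
  out$z_adj <- z_adj
  out$p_adj <- 2 * stats::pnorm(-abs(z_adj))
  if (!is.null(ewas_table$effect)) {
    out$se_adj <- ifelse(z_adj == 0, NA_real_, ewas_table$effect / z_adj)
  }
  out
}
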