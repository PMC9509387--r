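#' Synthetic cortical methylation cohorts with known ground truth
#'
#' The `simcohort` generators emulate the statistical structure of a bulk
#' cortex DNA methylation study of neurodegeneration: three nuclei
#' populations (neuronal NeuN+, oligodendrocyte SOX10+, and a double-negative
#' microglia/astrocyte-enriched fraction, "DN") mixed in bulk tissue from two
#' cortical regions (DLPFC and OCC) per donor, correlated ordinal
#' neuropathology measures, pathology-coupled cell-proportion drift in the
#' DLPFC only, and differential methylation confined to chosen cell types.
#' Every generator is a pure function of its arguments and `seed`.
#'
#' @name simcohort
NULL

default_celltypes <- function() c("NeuN+", "SOX10+", "DN")

#' Generate cell-type mean methylation profiles with planted discriminating sites
#'
#' Builds per-probe, per-cell-type mean beta values. Most probes share a
#' common mean across cell types; for each cell type,
#' `n_discriminating_per_type` probes are flagged as discriminating, half
#' shifted up by `separation` in that cell type ("hyper") and half shifted
#' down ("hypo"). Means are constructed so no shift leaves [0,1]; impossible
#' separations raise an error rather than clipping.
#'
#' @param n_probes total number of probes.
#' @param n_celltypes number of cell types (default 3).
#' @param n_discriminating_per_type planted discriminating probes per cell type
#'   (must be even; half hyper, half hypo).
#' @param separation absolute beta difference between the flagged cell type and
#'   the others at a discriminating probe, in (0,1).
#' @param celltype_names cell-type identifiers.
#' @param within_sd_range range of per-probe within-cell-type dispersion on
#'   the logit scale, used when drawing replicate nuclei samples.
#' @param seed integer RNG seed.
#' @return An object of class `CellTypeProfiles`: list with `probe_ids`,
#'   `celltype_names`, `mean_beta` (probe x celltype), `within_type_sd`,
#'   `discriminating_mask` (logical probe x celltype), `direction`
#'   ("hyper"/"hypo"/NA).
#' @export
make_reference_profiles <- function(n_probes, n_celltypes = 3,
                                    n_discriminating_per_type = 100,
                                    separation = 0.5,
                                    celltype_names = NULL,
                                    within_sd_range = c(0.2, 0.4),
                                    seed = 1) {
  if (separation <= 0) stop("separation must be positive")
  if (separation >= 0.95) stop("separation too large: shifted means would leave [0,1]")
  if (n_discriminating_per_type %% 2 != 0) {
    stop("n_discriminating_per_type must be even (half hyper, half hypo)")
  }
  if (n_discriminating_per_type * n_celltypes > n_probes) {
    stop("n_discriminating_per_type * n_celltypes must not exceed n_probes")
  }
  if (is.null(celltype_names)) {
    celltype_names <- if (n_celltypes == 3) default_celltypes() else
      paste0("CT", seq_len(n_celltypes))
  }
  stopifnot(length(celltype_names) == n_celltypes)
  eps <- 0.02
  with_local_seed(seed, {
    probe_ids <- sprintf("cg%07d", seq_len(n_probes))
    base <- stats::runif(n_probes, eps, 1 - eps)
    mean_beta <- matrix(base, n_probes, n_celltypes,
                        dimnames = list(probe_ids, celltype_names))
    mask <- matrix(FALSE, n_probes, n_celltypes,
                   dimnames = list(probe_ids, celltype_names))
    direction <- matrix(NA_character_, n_probes, n_celltypes,
                        dimnames = list(probe_ids, celltype_names))
    half <- n_discriminating_per_type %/% 2
    disc_idx <- sample.int(n_probes, n_discriminating_per_type * n_celltypes)
    for (k in seq_len(n_celltypes)) {
      idx <- disc_idx[((k - 1) * n_discriminating_per_type + 1):
                        (k * n_discriminating_per_type)]
      hyper <- idx[seq_len(half)]
      hypo <- idx[(half + 1):(2 * half)]
      # redraw shared means so the shifted value stays inside [eps, 1 - eps]
      mean_beta[hyper, ] <- stats::runif(length(hyper), eps, 1 - eps - separation)
      mean_beta[hypo, ] <- stats::runif(length(hypo), eps + separation, 1 - eps)
      mean_beta[hyper, k] <- mean_beta[hyper, 1] + separation
      mean_beta[hypo, k] <- mean_beta[hypo, 1] - separation
      # restore the common value in non-target columns (shared across others)
      others <- setdiff(seq_len(n_celltypes), k)
      mean_beta[c(hyper, hypo), others] <-
        mean_beta[c(hyper, hypo), others[1]]
      mask[idx, k] <- TRUE
      direction[hyper, k] <- "hyper"
      direction[hypo, k] <- "hypo"
    }
    structure(list(
      probe_ids = probe_ids,
      celltype_names = celltype_names,
      mean_beta = mean_beta,
      within_type_sd = stats::runif(n_probes, within_sd_range[1], within_sd_range[2]),
      discriminating_mask = mask,
      direction = direction,
      separation = separation
    ), class = "CellTypeProfiles")
  })
}

#' Draw replicate nuclei methylation samples from cell-type profiles
#'
#' Emulates sorted-nuclei reference data: for each cell type,
#' `n_per_type` replicate samples are drawn around the cell-type mean with
#' logit-normal dispersion `within_type_sd`.
#'
#' @param profiles a `CellTypeProfiles` object.
#' @param n_per_type replicates per cell type (default 12, the size of a
#'   typical sorted-nuclei reference set).
#' @param seed integer RNG seed.
#' @return list with `beta` (probe x sample matrix) and `celltype` labels.
#' @export
simulate_reference_samples <- function(profiles, n_per_type = 12, seed = 1) {
  stopifnot(inherits(profiles, "CellTypeProfiles"), n_per_type >= 2)
  with_local_seed(seed, {
    k <- length(profiles$celltype_names)
    np <- length(profiles$probe_ids)
    beta <- matrix(NA_real_, np, k * n_per_type)
    labels <- character(k * n_per_type)
    cols <- character(k * n_per_type)
    j <- 0L
    for (ct in seq_len(k)) {
      mu <- logit(pmin(pmax(profiles$mean_beta[, ct], 1e-6), 1 - 1e-6))
      for (r in seq_len(n_per_type)) {
        j <- j + 1L
        beta[, j] <- expit(mu + stats::rnorm(np, 0, profiles$within_type_sd))
        labels[j] <- profiles$celltype_names[ct]
        cols[j] <- sprintf("ref_%s_%02d", gsub("[^A-Za-z0-9]", "", labels[j]), r)
      }
    }
    dimnames(beta) <- list(profiles$probe_ids, cols)
    list(beta = beta, celltype = labels)
  })
}

# Beta-binomial category probabilities matched to an ordinal mean and SD;
# used to reproduce the marginal distributions of staged pathology scores.
beta_binomial_probs <- function(n_max, mean, sd) {
  p <- mean / n_max
  v <- sd^2
  rho <- (v / (n_max * p * (1 - p)) - 1) / (n_max - 1)
  if (!is.finite(rho) || rho <= 0 || rho >= 1) {
    stop("mean/sd combination not representable by a beta-binomial on this range")
  }
  ab <- 1 / rho - 1
  a <- p * ab
  b <- (1 - p) * ab
  k <- 0:n_max
  pr <- choose(n_max, k) * beta(k + a, n_max - k + b) / beta(a, b)
  pr / sum(pr)
}

#' Default marginal distributions for the five neuropathology measures
#'
#' Category probabilities for Braak NFT stage (0-6), CERAD score (0-3),
#' Thal phase (0-5) and Braak Lewy-body stage (0-6) as beta-binomials matched
#' to cohort-typical means/SDs (Braak 3.72/1.90, CERAD 1.69/1.28,
#' Thal 3.09/1.78, LB 1.34/2.26), plus a TDP-43 positivity rate of 0.22.
#'
#' @return named list of category probability vectors (tdp43 is a single rate).
#' @export
default_pathology_marginals <- function() {
  list(
    braak_nft = beta_binomial_probs(6, 3.72, 1.90),
    cerad = beta_binomial_probs(3, 1.69, 1.28),
    thal = beta_binomial_probs(5, 3.09, 1.78),
    braak_lb = beta_binomial_probs(6, 1.34, 2.26),
    tdp43 = 0.22
  )
}

#' Default latent correlation among the five pathology measures
#' @return 5 x 5 correlation matrix (braak_nft, cerad, thal, braak_lb, tdp43).
#' @export
default_pathology_correlation <- function() {
  m <- diag(5)
  nm <- c("braak_nft", "cerad", "thal", "braak_lb", "tdp43")
  dimnames(m) <- list(nm, nm)
  ad <- c("braak_nft", "cerad", "thal")
  m[ad, ad] <- 0.7
  diag(m) <- 1
  m["braak_lb", ad] <- m[ad, "braak_lb"] <- 0.15
  m["tdp43", ad] <- m[ad, "tdp43"] <- 0.25
  m["braak_lb", "tdp43"] <- m["tdp43", "braak_lb"] <- 0.30
  m
}

#' Generate correlated ordinal neuropathology measures per donor
#'
#' Draws a latent Gaussian vector per donor with the given correlation matrix
#' and thresholds each coordinate into its ordinal range so that the marginal
#' category probabilities match `marginals` (a Gaussian copula).
#'
#' @param n_donors number of donors.
#' @param correlation 5 x 5 positive semi-definite latent correlation matrix
#'   in the order braak_nft, cerad, thal, braak_lb, tdp43.
#' @param marginals list of marginal category probabilities as produced by
#'   [default_pathology_marginals()].
#' @param seed integer RNG seed.
#' @return data.frame with donor_id, braak_nft (0-6), cerad (0-3), thal (0-5),
#'   braak_lb (0-6) and tdp43 (0/1).
#' @export
make_pathology <- function(n_donors,
                           correlation = default_pathology_correlation(),
                           marginals = default_pathology_marginals(),
                           seed = 1) {
  if (!is.matrix(correlation) || nrow(correlation) != 5 ||
      ncol(correlation) != 5 ||
      max(abs(correlation - t(correlation))) > 1e-8 ||
      any(abs(diag(correlation) - 1) > 1e-8)) {
    stop("invalid correlation matrix: must be symmetric 5x5 with unit diagonal")
  }
  ev <- eigen(correlation, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("invalid correlation matrix: not positive semi-definite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)))
  with_local_seed(seed, {
    z <- matrix(stats::rnorm(n_donors * 5), n_donors, 5) %*% t(L)
    thr <- function(p) stats::qnorm(cumsum(p)[-length(p)])
    ord <- function(zj, p) findInterval(zj, thr(p))
    data.frame(
      donor_id = sprintf("D%04d", seq_len(n_donors)),
      braak_nft = ord(z[, 1], marginals$braak_nft),
      cerad = ord(z[, 2], marginals$cerad),
      thal = ord(z[, 3], marginals$thal),
      braak_lb = ord(z[, 4], marginals$braak_lb),
      tdp43 = as.integer(z[, 5] > stats::qnorm(1 - marginals$tdp43)),
      stringsAsFactors = FALSE
    )
  })
}

#' Specify cell-type-confined differential methylation
#'
#' Describes true differential methylation injected by the generators: at
#' `target_probes`, methylation within `target_celltype` shifts by
#' `sign * effect_per_unit` percentage points per unit of `driving_measure`.
#' In bulk tissue the observable effect is attenuated by the cell type's
#' mixture proportion.
#'
#' @param target_probes probe identifiers.
#' @param target_celltype a single cell-type name.
#' @param effect_per_unit percentage points of methylation per unit of the
#'   driving measure (default 0.44); recycled over probes.
#' @param driving_measure one of braak_nft, cerad, thal, braak_lb, tdp43.
#' @param sign +1/-1 per probe (recycled).
#' @return An `EffectSpec` object.
#' @export
effect_spec <- function(target_probes, target_celltype,
                        effect_per_unit = 0.44,
                        driving_measure = "braak_nft",
                        sign = 1) {
  driving_measure <- match.arg(driving_measure,
                               c("braak_nft", "cerad", "thal", "braak_lb", "tdp43"))
  n <- length(target_probes)
  structure(list(
    target_probes = as.character(target_probes),
    target_celltype = target_celltype,
    effect_per_unit = rep_len(effect_per_unit, n),
    driving_measure = driving_measure,
    sign = rep_len(sign, n)
  ), class = "EffectSpec")
}

#' Draw per-probe effect magnitudes around the cohort-typical value
#'
#' Magnitudes are drawn from a normal with mean 0.44 and SD 0.17 percentage
#' points per Braak stage (truncated at a small positive floor), mirroring
#' the spread of per-stage effect sizes at tau-associated differentially
#' methylated positions.
#'
#' @param n number of probes.
#' @param mean,sd normal parameters, percentage points per unit.
#' @param seed integer RNG seed.
#' @return numeric vector of positive magnitudes.
#' @export
draw_effect_sizes <- function(n, mean = 0.44, sd = 0.17, seed = 1) {
  with_local_seed(seed, pmax(stats::rnorm(n, mean, sd), 0.05))
}

#' Choose probes suitable for planting effects
#'
#' Returns non-discriminating probes with common mean in a mid-range band, so
#' that injected shifts never leave [0,1].
#' @param profiles `CellTypeProfiles`.
#' @param n number of probes.
#' @param range admissible mean-beta band.
#' @param seed integer RNG seed.
#' @export
pick_effect_probes <- function(profiles, n, range = c(0.2, 0.8), seed = 1) {
  ok <- !apply(profiles$discriminating_mask, 1, any) &
    profiles$mean_beta[, 1] >= range[1] & profiles$mean_beta[, 1] <= range[2]
  ids <- profiles$probe_ids[ok]
  if (length(ids) < n) stop("not enough mid-range non-discriminating probes")
  with_local_seed(seed, sample(ids, n))
}

# Apply one EffectSpec (or a list of them, e.g. a main effect in one cell
# type plus a secondary effect in another) to the profile mean matrix for one
# sample; errors if a shifted mean leaves [0,1] (no silent clipping).
apply_effect <- function(mean_beta, spec, measure_value) {
  if (is.null(spec)) return(mean_beta)
  if (inherits(spec, "EffectSpec")) spec <- list(spec)
  for (sp in spec) {
    shift <- sp$sign * sp$effect_per_unit / 100 * measure_value
    ct <- sp$target_celltype
    v <- mean_beta[sp$target_probes, ct] + shift
    if (any(v < 0 | v > 1)) {
      stop("effect spec drives a cell-type mean outside [0,1]")
    }
    mean_beta[sp$target_probes, ct] <- v
  }
  mean_beta
}

#' Default pathology-proportion coupling (percentage points per Braak stage)
#'
#' NeuN+ falls by 2.74, SOX10+ rises by 1.60 and the double-negative fraction
#' falls by 2.00 percentage points per Braak NFT stage in the DLPFC;
#' the OCC is uncoupled.
#' @export
default_proportion_coupling <- function() {
  c("NeuN+" = -2.74, "SOX10+" = 1.60, "DN" = -2.00)
}

#' Generate a bulk two-region methylation cohort
#'
#' For each donor, cell proportions are drawn from a Dirichlet around base
#' means (with residual mass treated as unmodeled debris); in the DLPFC only,
#' the Dirichlet means shift linearly with Braak NFT stage (centered at stage
#' 3) by `proportion_coupling`. Bulk beta is the proportion-weighted mixture
#' of the cell-type means (including any `EffectSpec` shift confined to the
#' target cell type), plus logit-normal measurement noise. Detection p-values
#' are uniform on (0, 0.01) with a configurable failure rate producing values
#' near 1. Age, sex and batch covariates are assigned.
#'
#' @param profiles `CellTypeProfiles` (3 cell types for the default coupling).
#' @param n_donors number of donors; each contributes one sample per region.
#' @param regions subset of c("DLPFC","OCC").
#' @param effect_spec optional `EffectSpec`.
#' @param proportion_coupling named vector of per-stage shifts in percentage
#'   points applied in DLPFC (NULL for no coupling).
#' @param coupling_center Braak stage at which coupled means equal the base
#'   means (default 3, near the cohort mean stage).
#' @param base_props base mean proportions per cell type (sum < 1; the
#'   remainder is debris mass).
#' @param concentration Dirichlet concentration (total).
#' @param noise_sd logit-scale measurement noise SD (0 allowed for noiseless
#'   algebra checks).
#' @param detp_fail_rate probability a (probe, sample) detection fails.
#' @param pathology optional pre-generated pathology table (from
#'   [make_pathology()]); generated from a child seed if NULL.
#' @param seed integer RNG seed.
#' @return list of class `cohort`: `beta`, `detp` (probe x sample),
#'   `pheno` (sample_id, donor_id, region, age, sex, batch + five measures),
#'   `true_props` (sample_id + one column per cell type).
#' @export
make_cohort <- function(profiles, n_donors,
                        regions = c("DLPFC", "OCC"),
                        effect_spec = NULL,
                        proportion_coupling = default_proportion_coupling(),
                        coupling_center = 3,
                        base_props = c("NeuN+" = 0.42, "SOX10+" = 0.37, "DN" = 0.10),
                        concentration = 200,
                        noise_sd = 0.1,
                        detp_fail_rate = 0.001,
                        pathology = NULL,
                        seed = 1) {
  stopifnot(inherits(profiles, "CellTypeProfiles"))
  if (!all(regions %in% c("DLPFC", "OCC")) || length(regions) < 1) {
    stop("regions must be a subset of c('DLPFC','OCC')")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  k <- length(profiles$celltype_names)
  base_props <- base_props[profiles$celltype_names]
  if (anyNA(base_props)) stop("base_props must be named by the profile cell types")
  if (sum(base_props) >= 1) stop("base_props must sum to < 1 (debris remainder)")
  if (is.null(pathology)) {
    pathology <- make_pathology(n_donors, seed = child_seed(seed, 1))
  }
  stopifnot(nrow(pathology) == n_donors)
  np <- length(profiles$probe_ids)

  with_local_seed(child_seed(seed, 2), {
    age <- pmin(pmax(round(stats::rnorm(n_donors, 84, 8)), 41), 104)
    sex <- ifelse(stats::runif(n_donors) < 0.53, "M", "F")
    n_samples <- n_donors * length(regions)
    sample_id <- character(n_samples)
    beta <- matrix(NA_real_, np, n_samples)
    detp <- matrix(NA_real_, np, n_samples)
    props <- matrix(NA_real_, n_samples, k)
    ph <- vector("list", n_samples)
    j <- 0L
    for (d in seq_len(n_donors)) {
      for (rg in regions) {
        j <- j + 1L
        sample_id[j] <- sprintf("%s_%s", pathology$donor_id[d], rg)
        braak <- pathology$braak_nft[d]
        m <- base_props
        if (identical(rg, "DLPFC") && !is.null(proportion_coupling)) {
          pc <- proportion_coupling[profiles$celltype_names]
          pc[is.na(pc)] <- 0
          m <- base_props + pc / 100 * (braak - coupling_center)
        }
        if (any(m <= 0)) {
          stop("proportion coupling drives a cell-type proportion negative; ",
               "re-truncation is not performed")
        }
        if (sum(m) >= 1) {
          stop("proportion coupling drives the proportion sum to >= 1")
        }
        pi_j <- rdirichlet(1, concentration * c(m, 1 - sum(m)))[1, seq_len(k)]
        props[j, ] <- pi_j
        mv <- if (is.null(effect_spec)) 0 else pathology[[effect_spec$driving_measure]][d]
        M <- apply_effect(profiles$mean_beta, effect_spec, mv)
        mu <- as.vector(M %*% pi_j)
        mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
        beta[, j] <- if (noise_sd > 0) {
          expit(logit(mu) + stats::rnorm(np, 0, noise_sd))
        } else mu
        fail <- stats::runif(np) < detp_fail_rate
        detp[, j] <- ifelse(fail, stats::runif(np, 0.9, 1), stats::runif(np, 0, 0.01))
        ph[[j]] <- data.frame(
          sample_id = sample_id[j], donor_id = pathology$donor_id[d],
          region = rg, age = age[d], sex = sex[d],
          batch = sprintf("B%d", sample.int(4, 1)),
          pathology[d, -1, drop = FALSE],
          stringsAsFactors = FALSE, row.names = NULL
        )
      }
    }
    dimnames(beta) <- list(profiles$probe_ids, sample_id)
    dimnames(detp) <- list(profiles$probe_ids, sample_id)
    colnames(props) <- profiles$celltype_names
    structure(list(
      beta = beta,
      detp = detp,
      pheno = do.call(rbind, ph),
      true_props = data.frame(sample_id = sample_id, props,
                              check.names = FALSE, stringsAsFactors = FALSE),
      effect_spec = effect_spec
    ), class = "cohort")
  })
}

#' Generate a sorted-nuclei fraction study with low/high pathology groups
#'
#' Emulates fluorescence-activated nuclei sorting of DLPFC tissue from
#' low-pathology (Braak stage <= II) and high-pathology (Braak stage >= V)
#' donors: for each donor a beta matrix is produced for the total (bulk-like)
#' fraction and for each purified population. Purified fractions carry any
#' cell-type-confined effect at full magnitude; the total fraction carries it
#' attenuated by the mixture proportion.
#'
#' @param profiles `CellTypeProfiles`.
#' @param n_low,n_high donors per group (defaults 15 low / 13 high).
#' @param effect_spec optional `EffectSpec` (driving measure braak_nft).
#' @param base_props,concentration,noise_sd as in [make_cohort()].
#' @param seed integer RNG seed.
#' @return list with `fractions` (named list of probe x donor beta matrices:
#'   "total" plus one per cell type), `labels` (sample_id, group, braak_nft,
#'   age, sex, batch) and `true_props` for the total fraction.
#' @export
make_sorted_fraction_study <- function(profiles, n_low = 15, n_high = 13,
                                       effect_spec = NULL,
                                       base_props = c("NeuN+" = 0.42, "SOX10+" = 0.37, "DN" = 0.10),
                                       concentration = 200,
                                       noise_sd = 0.1,
                                       seed = 1) {
  stopifnot(inherits(profiles, "CellTypeProfiles"))
  if (n_low < 2 || n_high < 2) stop("n_low and n_high must both be >= 2")
  k <- length(profiles$celltype_names)
  base_props <- base_props[profiles$celltype_names]
  if (anyNA(base_props) || sum(base_props) >= 1) {
    stop("base_props must be named by the profile cell types and sum to < 1")
  }
  np <- length(profiles$probe_ids)
  n <- n_low + n_high
  with_local_seed(seed, {
    group <- c(rep("low", n_low), rep("high", n_high))
    braak <- c(sample(0:2, n_low, replace = TRUE), sample(5:6, n_high, replace = TRUE))
    age <- pmin(pmax(round(stats::rnorm(n, 81, 8)), 55), 101)
    sex <- ifelse(stats::runif(n) < 0.5, "M", "F")
    batch <- sprintf("B%d", sample.int(3, n, replace = TRUE))
    ids <- sprintf("F%03d", seq_len(n))
    fracs <- c("total", profiles$celltype_names)
    out <- lapply(fracs, function(f)
      matrix(NA_real_, np, n, dimnames = list(profiles$probe_ids, ids)))
    names(out) <- fracs
    props <- matrix(NA_real_, n, k, dimnames = list(ids, profiles$celltype_names))
    for (j in seq_len(n)) {
      M <- apply_effect(profiles$mean_beta, effect_spec, braak[j])
      pi_j <- rdirichlet(1, concentration * c(base_props, 1 - sum(base_props)))[1, seq_len(k)]
      props[j, ] <- pi_j
      mu_total <- pmin(pmax(as.vector(M %*% pi_j), 1e-12), 1 - 1e-12)
      out[["total"]][, j] <- if (noise_sd > 0) {
        expit(logit(mu_total) + stats::rnorm(np, 0, noise_sd))
      } else mu_total
      for (ct in profiles$celltype_names) {
        mu <- pmin(pmax(M[, ct], 1e-12), 1 - 1e-12)
        out[[ct]][, j] <- if (noise_sd > 0) {
          expit(logit(mu) + stats::rnorm(np, 0, noise_sd))
        } else mu
      }
    }
    list(
      fractions = out,
      labels = data.frame(sample_id = ids, group = group, braak_nft = braak,
                          age = age, sex = sex, batch = batch,
                          stringsAsFactors = FALSE),
      true_props = data.frame(sample_id = ids, props, check.names = FALSE,
                              stringsAsFactors = FALSE)
    )
  })
}
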