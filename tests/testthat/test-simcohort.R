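test_that("reference profiles honor the flag contract and are deterministic", {
  prof <- make_reference_profiles(300, 3, 60, separation = 0.5, seed = 1)
  expect_equal(sum(prof$discriminating_mask), 180)
  for (ct in prof$celltype_names) {
    expect_equal(sum(prof$direction[, ct] == "hyper", na.rm = TRUE), 30)
    expect_equal(sum(prof$direction[, ct] == "hypo", na.rm = TRUE), 30)
  }
  expect_true(all(prof$mean_beta >= 0 & prof$mean_beta <= 1))
  expect_true(all(prof$within_type_sd > 0))
  # planted separation realized exactly
  for (ct in prof$celltype_names) {
    idx <- which(prof$discriminating_mask[, ct])
    others <- setdiff(prof$celltype_names, ct)
    diffs <- prof$mean_beta[idx, ct] - prof$mean_beta[idx, others[1]]
    expect_true(all(abs(abs(diffs) - 0.5) < 1e-12))
  }
  prof2 <- make_reference_profiles(300, 3, 60, separation = 0.5, seed = 1)
  expect_identical(prof, prof2)
  expect_error(make_reference_profiles(300, 3, 60, separation = 0),
               "separation must be positive")
  expect_error(make_reference_profiles(100, 3, 60, separation = 0.5),
               "must not exceed")
})

test_that("pathology measures stay in range with positive rank correlations", {
  path <- make_pathology(631, seed = 7)
  expect_true(all(path$braak_nft %in% 0:6))
  expect_true(all(path$cerad %in% 0:3))
  expect_true(all(path$thal %in% 0:5))
  expect_true(all(path$braak_lb %in% 0:6))
  expect_true(all(path$tdp43 %in% 0:1))
  expect_gt(cor(path$braak_nft, path$cerad, method = "spearman"), 0)
  expect_gt(cor(path$braak_nft, path$thal, method = "spearman"), 0)
  # marginal mean matches the cohort-typical Braak mean
  expect_lt(abs(mean(path$braak_nft) - 3.72), 0.2)
})

test_that("identity latent correlation yields near-independent measures", {
  path <- make_pathology(2000, correlation = diag(5), seed = 3)
  expect_lt(abs(cor(path$braak_nft, path$cerad, method = "spearman")), 0.1)
  expect_lt(abs(cor(path$braak_nft, path$thal, method = "spearman")), 0.1)
})

test_that("invalid correlation matrices are rejected", {
  bad <- diag(5)
  bad[1, 2] <- 0.5 # asymmetric
  expect_error(make_pathology(10, correlation = bad), "symmetric")
  bad2 <- matrix(0.99, 5, 5)
  diag(bad2) <- 1
  bad2[1, 2] <- bad2[2, 1] <- -0.99 # indefinite
  expect_error(make_pathology(10, correlation = bad2), "positive semi-definite")
})

test_that("cohorts have two rows per donor and bounded values", {
  prof <- fix_profiles(200, 30, seed = 4)
  co <- make_cohort(prof, 50, seed = 5)
  expect_equal(dim(co$beta), c(200, 100))
  expect_equal(nrow(co$pheno), 100)
  expect_equal(as.integer(table(co$pheno$donor_id)), rep(2L, 50))
  expect_setequal(unique(co$pheno$region), c("DLPFC", "OCC"))
  expect_true(all(co$beta > 0 & co$beta < 1))
  props <- as.matrix(co$true_props[, prof$celltype_names])
  expect_true(all(props >= 0))
  expect_true(all(rowSums(props) <= 1))
  co2 <- make_cohort(prof, 50, seed = 5)
  expect_identical(co$beta, co2$beta)
})

test_that("excessive proportion coupling raises instead of truncating", {
  prof <- fix_profiles(100, 20, seed = 6)
  expect_error(
    make_cohort(prof, 30, base_props = c("NeuN+" = 0.42, "SOX10+" = 0.37, "DN" = 0.04),
                seed = 6),
    "negative")
})

test_that("null cohorts give uniform composition-adjusted p-values", {
  prof <- fix_profiles(2000, 60, seed = 8)
  co <- make_cohort(prof, 120, proportion_coupling = NULL, seed = 9)
  # per-probe regression of beta on Braak stage given the true cell
  # composition (methylation depends on pathology only through composition,
  # so the conditional association is exactly null and probe-wise independent)
  X <- cbind(1, co$pheno$braak_nft,
             as.matrix(co$true_props[, prof$celltype_names]))
  qX <- qr(X)
  cf <- qr.coef(qX, t(co$beta))
  rss <- colSums(qr.resid(qX, t(co$beta))^2)
  xtx_inv <- chol2inv(qr.R(qX))
  se <- sqrt(xtx_inv[2, 2] * rss / (nrow(X) - ncol(X)))
  tv <- cf[2, ] / se
  p <- 2 * stats::pt(-abs(tv), nrow(X) - ncol(X))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("bulk attenuation equals mean proportion times cell-level effect", {
  prof <- fix_profiles(300, 40, seed = 10)
  targ <- pick_effect_probes(prof, 25, range = c(0.3, 0.7), seed = 11)
  es <- effect_spec(targ, "DN", effect_per_unit = 4, sign = 1)
  co <- make_cohort(prof, 60, effect_spec = es, proportion_coupling = NULL,
                    noise_sd = 0, seed = 12)
  base <- make_cohort(prof, 60, effect_spec = NULL, proportion_coupling = NULL,
                      noise_sd = 0, seed = 12)
  braak <- co$pheno$braak_nft
  pi_dn <- co$true_props$DN
  nz <- braak > 0
  # per-sample implied cell-level contribution: (bulk - baseline)/braak = pi_DN * e
  for (t in targ[1:5]) {
    implied <- (co$beta[t, nz] - base$beta[t, nz]) / braak[nz]
    expect_lt(max(abs(implied - pi_dn[nz] * 0.04)), 1e-10)
  }
  # averaged over samples: the attenuation law
  t1 <- targ[1]
  implied <- (co$beta[t1, nz] - base$beta[t1, nz]) / braak[nz]
  expect_lt(abs(mean(implied) - mean(pi_dn[nz]) * 0.04), 1e-10)
})

test_that("effects that leave [0,1] are rejected", {
  prof <- fix_profiles(100, 20, seed = 13)
  hi <- prof$probe_ids[which(prof$mean_beta[, "DN"] > 0.9)][1]
  es <- effect_spec(hi, "DN", effect_per_unit = 4, sign = 1)
  expect_error(make_cohort(prof, 30, effect_spec = es, seed = 13),
               "outside \\[0,1\\]")
})

test_that("sorted-fraction studies carry full effects in the target fraction", {
  prof <- fix_profiles(200, 30, seed = 14)
  targ <- pick_effect_probes(prof, 10, range = c(0.3, 0.7), seed = 15)
  es <- effect_spec(targ, "DN", effect_per_unit = 4, sign = 1)
  sf <- make_sorted_fraction_study(prof, n_low = 15, n_high = 13,
                                   effect_spec = es, noise_sd = 0, seed = 16)
  expect_equal(ncol(sf$fractions$total), 28)
  expect_named(sf$fractions, c("total", prof$celltype_names))
  lo <- sf$labels$group == "low"
  hi <- sf$labels$group == "high"
  d_braak <- mean(sf$labels$braak_nft[hi]) - mean(sf$labels$braak_nft[lo])
  # purified DN fraction: full-magnitude effect
  d_dn <- rowMeans(sf$fractions$DN[targ, hi]) - rowMeans(sf$fractions$DN[targ, lo])
  expect_lt(max(abs(d_dn - 0.04 * d_braak)), 1e-10)
  # total fraction: attenuated by mean DN proportion
  d_tot <- rowMeans(sf$fractions$total[targ, hi]) - rowMeans(sf$fractions$total[targ, lo])
  atten <- d_tot / d_dn
  expect_lt(abs(mean(atten) - mean(sf$true_props$DN)), 0.03)
  expect_error(make_sorted_fraction_study(prof, n_low = 1, n_high = 5),
               ">= 2")
  sf2 <- make_sorted_fraction_study(prof, n_low = 15, n_high = 13,
                                    effect_spec = es, noise_sd = 0, seed = 16)
  expect_identical(sf$fractions$total, sf2$fractions$total)
})

test_that("drawn effect magnitudes center on the typical per-stage effect", {
  e <- draw_effect_sizes(5000, seed = 17)
  expect_lt(abs(mean(e) - 0.44), 0.02)
  expect_true(all(e > 0))
})
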