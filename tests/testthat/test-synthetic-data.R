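test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(frac_shifted = 1.2), "proportions")
  expect_error(sim_config(frac_copurifying = -0.1), "proportions")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(shift_log2 = Inf), "finite")
  expect_error(sim_config(genotypes = "wildtype"), "two genotypes")
  expect_error(sim_config(peptides_per_protein = c(5, 2)), "range")
  expect_error(sim_config(focal_lipid_class = "XYZ"), "focal_lipid_class")
})

test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- small_cfg(seed = 7)
  a <- simulate_evidence(cfg)
  b <- simulate_evidence(cfg)
  expect_identical(a, b)
  la <- simulate_lipids(cfg)
  lb <- simulate_lipids(cfg)
  expect_identical(la, lb)
  cfg2 <- small_cfg(seed = 8)
  expect_false(identical(simulate_evidence(cfg2)$evidence, a$evidence))
})

test_that("null noiseless dataset has genotype-invariant DRM/DSF ratios", {
  cfg <- small_cfg(n_proteins = 20, frac_shifted = 0, frac_copurifying = 0,
                   noise_cv = 0, coupling = FALSE,
                   missing_model = list(enabled = FALSE), seed = 2)
  sim <- simulate_evidence(cfg)
  ev <- sim$evidence; d <- sim$design
  ratio <- function(geno, pep) {
    drm <- ev$intensity[ev$peptide_id == pep & ev$sample_id %in%
                          d$sample_id[d$genotype == geno & d$fraction == "DRM"]]
    dsf <- ev$intensity[ev$peptide_id == pep & ev$sample_id %in%
                          d$sample_id[d$genotype == geno & d$fraction == "DSF"]]
    mean(drm) / mean(dsf)
  }
  peps <- unique(ev$peptide_id)
  for (pep in sample(peps, 10))
    expect_equal(ratio("wildtype", pep), ratio("mutant", pep))
})

test_that("planted shift forces the exact DRM/DSF ratio change", {
  cfg <- small_cfg(n_proteins = 1, frac_shifted = 1, shift_log2 = 2,
                   frac_copurifying = 0, noise_cv = 0, coupling = FALSE,
                   missing_model = list(enabled = FALSE), seed = 3)
  sim <- simulate_evidence(cfg)
  sgn <- sign(sim$truth$shifted_proteins$shift_log2[1])
  ev <- sim$evidence; d <- sim$design
  pep <- ev$peptide_id[1]
  r_of <- function(geno) {
    drm <- ev$intensity[ev$peptide_id == pep & ev$sample_id %in%
                          d$sample_id[d$genotype == geno & d$fraction == "DRM"]][1]
    dsf <- ev$intensity[ev$peptide_id == pep & ev$sample_id %in%
                          d$sample_id[d$genotype == geno & d$fraction == "DSF"]][1]
    drm / dsf
  }
  expect_equal(r_of("mutant") / r_of("wildtype"), 4^sgn)
})

test_that("ground truth ratios are reproduced exactly from noiseless tables", {
  cfg <- small_cfg(n_proteins = 12, frac_shifted = 0.5, shift_log2 = 1.5,
                   noise_cv = 0, coupling = FALSE,
                   missing_model = list(enabled = FALSE), seed = 4)
  sim <- simulate_evidence(cfg)
  ev <- sim$evidence; d <- sim$design
  exp_tab <- sim$truth$expected_log2_drmdsf
  for (i in sample(nrow(exp_tab), 8)) {
    pr <- exp_tab$protein_id[i]; geno <- exp_tab$genotype[i]
    pep <- ev$peptide_id[ev$protein_id == pr][1]
    drm <- ev$intensity[ev$peptide_id == pep & ev$sample_id %in%
                          d$sample_id[d$genotype == geno & d$fraction == "DRM"]][1]
    dsf <- ev$intensity[ev$peptide_id == pep & ev$sample_id %in%
                          d$sample_id[d$genotype == geno & d$fraction == "DSF"]][1]
    expect_equal(log2(drm / dsf), exp_tab$log2_drmdsf[i])
  }
})

test_that("realized dropout matches the logistic model's expectation", {
  # ~2000+ potential observations; expected rate and its SE come from the
  # per-observation dropout probabilities integrated by the generator
  cfg <- small_cfg(n_proteins = 50, peptides_per_protein = c(3L, 5L),
                   noise_cv = 0.2, seed = 5)
  sim <- simulate_evidence(cfg)
  dr <- sim$truth$dropout
  expect_gt(dr$n_potential, 2000)
  realized <- 1 - nrow(sim$evidence) / dr$n_potential
  expect_lt(abs(realized - dr$expected_rate), 3 * dr$se)
})

test_that("null lipid tables have exactly equal genotype means at zero noise", {
  cfg <- small_cfg(n_diff_lipids = 0, noise_cv = 0, coupling = FALSE, seed = 6)
  lip <- simulate_lipids(cfg)
  m <- merge_modes(lip$pos, lip$neg)
  wt <- lip$design$sample_id[lip$design$genotype == "wildtype"]
  mu <- lip$design$sample_id[lip$design$genotype == "mutant"]
  expect_equal(rowMeans(m$intensity[, wt]), rowMeans(m$intensity[, mu]))
})

test_that("planted lipid fold change is exact without noise", {
  cfg <- small_cfg(n_diff_lipids = 1, lipid_fc_log2 = -1, noise_cv = 0,
                   coupling = FALSE, focal_lipid_class = "GlcCer", seed = 7)
  lip <- simulate_lipids(cfg)
  tr <- lip$truth$differential_lipids
  expect_equal(tr$class, "GlcCer")
  m <- merge_modes(lip$pos, lip$neg)
  id <- grep(tr$lipid_id, m$meta$lipid_id, fixed = TRUE, value = FALSE)[1]
  wt <- lip$design$sample_id[lip$design$genotype == "wildtype"]
  mu <- lip$design$sample_id[lip$design$genotype == "mutant"]
  expect_equal(mean(m$intensity[id, mu]) / mean(m$intensity[id, wt]),
               2^tr$fc_log2[1])
})

test_that("log2FC recovery matches the analytic noise model over seeds", {
  # analytic oracle: with log-normal noise at CV tau and n replicates per
  # group, the log2FC estimator is approximately normal with
  # sd = sqrt(2) * sdlog/sqrt(n) / ln 2; the spec-level figure of 95%
  # within +/-0.15 at n=4, CV 0.1 is unattainable (analytic coverage ~86%);
  # we assert the realized coverage matches the oracle within MC slack.
  n_rep <- 4L; tau <- 0.1; tol <- 0.15
  sdlog <- sqrt(log(1 + tau^2))
  cover_pred <- 2 * stats::pnorm(tol / (sqrt(2) * sdlog / sqrt(n_rep) / log(2))) - 1
  errs <- unlist(lapply(1:60, function(s) {
    cfg <- small_cfg(n_lipids_per_class = 2L, n_diff_lipids = 5L,
                     lipid_fc_log2 = 1, noise_cv = tau,
                     n_lipid_replicates = n_rep, coupling = FALSE, seed = s)
    lip <- simulate_lipids(cfg)
    m <- merge_modes(lip$pos, lip$neg)
    tr <- lip$truth$differential_lipids
    wt <- lip$design$sample_id[lip$design$genotype == "wildtype"]
    mu <- lip$design$sample_id[lip$design$genotype == "mutant"]
    vapply(seq_len(nrow(tr)), function(i) {
      rows <- which(m$meta$lipid_id == tr$lipid_id[i] |
                      startsWith(m$meta$lipid_id,
                                 paste0(tr$lipid_id[i], " [")))
      est <- log2(mean(m$intensity[rows[1], mu]) /
                    mean(m$intensity[rows[1], wt]))
      est - tr$fc_log2[i]
    }, numeric(1))
  }))
  expect_lt(abs(mean(errs)), 0.02)  # unbiased
  cover <- mean(abs(errs) <= tol)
  mc_se <- sqrt(cover_pred * (1 - cover_pred) / length(errs))
  expect_lt(abs(cover - cover_pred), 4 * mc_se)
})

test_that("peak simulation round-trips through correction and matching", {
  lib <- data.frame(name = sprintf("lip%02d", 1:12),
                    mz = seq(400, 950, 50), adduct = "[M+H]+",
                    rt = seq(1, 12, 1))
  # zero jitter, identity drift: every entry matched exactly
  pk <- simulate_peaks(lib, ppm_jitter = 0, seed = 1)
  m <- match_library(pk$peaks, lib)
  expect_setequal(m$matches$name, lib$name)
  expect_equal(m$matches$ppm, rep(0, 12))
  # +0.3 min drift still within 0.5 min tolerance; +1.0 min fails until
  # marker-based correction restores it
  pk3 <- simulate_peaks(lib, drift = function(t) t + 0.3, ppm_jitter = 0,
                        seed = 2)
  expect_setequal(match_library(pk3$peaks, lib)$matches$name, lib$name)
  pk10 <- simulate_peaks(lib, drift = function(t) t + 1.0, ppm_jitter = 0,
                         seed = 3)
  expect_length(match_library(pk10$peaks, lib)$matches$name, 0)
  corr <- rt_correct(pk10$peaks, pk10$markers)
  expect_setequal(match_library(corr, lib)$matches$name, lib$name)
  # decoys at 20 ppm: matched at 25 ppm, rejected at 5 ppm
  pkd <- simulate_peaks(lib, ppm_jitter = 0, n_decoys = 5,
                        decoy_ppm_offset = 20, seed = 4)
  strict <- match_library(pkd$peaks, lib, ppm_tol = 5)
  loose <- match_library(pkd$peaks, lib, ppm_tol = 25)
  decoy_rows <- which(is.na(pkd$truth))
  expect_true(all(decoy_rows %in% strict$unmatched_peaks))
  expect_false(any(decoy_rows %in% loose$unmatched_peaks))
})
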