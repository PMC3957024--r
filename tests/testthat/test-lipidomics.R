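mini_table <- function(x, classes, ids = NULL) {
  ids <- ids %||% sprintf("%s %d:0", classes, 30 + seq_along(classes))
  meta <- data.frame(lipid_id = ids, class = classes,
                     acyl_carbons = rep(34L, length(ids)),
                     double_bonds = rep(1L, length(ids)),
                     hydroxylation = rep(NA_integer_, length(ids)),
                     stringsAsFactors = FALSE)
  lipid_table(meta, x)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("mode merging conserves rows and disambiguates shared species", {
  x <- matrix(1:6, 2, 3, dimnames = list(NULL, c("s1", "s2", "s3")))
  pos <- mini_table(x, c("PC", "PE"), c("PC 34:1", "PE 34:1"))
  neg <- mini_table(x * 2, c("PG", "PC"), c("PG 34:1", "PC 34:1"))
  m <- merge_modes(pos, neg)
  expect_equal(nrow(m$intensity), 4)
  expect_setequal(m$meta$lipid_id,
                  c("PC 34:1 [pos]", "PE 34:1", "PG 34:1", "PC 34:1 [neg]"))
  # one empty table: identity
  empty <- mini_table(x[0, , drop = FALSE], character(0), character(0))
  expect_equal(merge_modes(pos, empty), pos)
  # conflicting class metadata for a shared id is an error
  neg_bad <- mini_table(x, c("PC", "PG"), c("PC 34:1", "PG 34:1"))
  neg_bad$meta$acyl_carbons[1] <- 36L
  expect_error(merge_modes(pos, neg_bad), "conflicting")
})

test_that("normalization uses the low-variation non-TAG reference set", {
  # three constant lipids + one high-CV lipid: denominator is the sum of
  # the three constants per sample (hand computation on a 4 x 3 table)
  x <- rbind(c(2, 2, 2), c(3, 3, 3), c(5, 5, 5), c(10, 100, 1000))
  colnames(x) <- c("s1", "s2", "s3")
  tab <- mini_table(x, c("PC", "PE", "PG", "PI"))
  # the zero-CV constants tie at the median CV: the non-strict fallback
  # selects exactly the three constants
  expect_warning(out <- normalize_lipids(tab), "falling back")
  expect_equal(unname(out$intensity),
               unname(sweep(x, 2, c(10, 10, 10), "/")))
  expect_setequal(attr(out, "reference_set"), tab$meta$lipid_id[1:3])
  # agreement with the longhand oracle on random tables
  set.seed(41)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    xr <- matrix(rlnorm(n * 4, log(10), 1), n, 4,
                 dimnames = list(NULL, paste0("s", 1:4)))
    cls <- sample(c("PC", "PE", "TAG"), n, replace = TRUE)
    if (sum(cls != "TAG") < 2) cls[1:2] <- "PC"
    tabr <- mini_table(xr, cls, sprintf("L%02d %d:0", seq_len(n), seq_len(n)))
    expect_equal(unname(quiet(normalize_lipids(tabr))$intensity),
                 unname(bf_normalize_lipids(tabr$meta, xr)))
  }
})

test_that("TAG is excluded from denominators but still normalized", {
  x <- rbind(c(2, 2), c(8, 8), c(100, 200))
  colnames(x) <- c("s1", "s2")
  tab <- mini_table(x, c("PC", "PE", "TAG"))
  out <- quiet(normalize_lipids(tab))
  expect_false(any(grepl("TAG", attr(out, "reference_set"))))
  expect_true(all(is.finite(out$intensity[3, ])))
})

test_that("all-tied CVs trigger the documented fallback", {
  # power-of-two multiples keep the CVs bitwise identical
  x <- rbind(c(2, 4), c(4, 8), c(8, 16))
  colnames(x) <- c("s1", "s2")
  tab <- mini_table(x, c("PC", "PE", "PG"))
  expect_warning(out <- normalize_lipids(tab), "fallback|reference set empty")
  expect_equal(colSums(out$intensity), c(s1 = 1, s2 = 1))
})

test_that("normalization is invariant to per-sample scaling", {
  set.seed(42)
  x <- matrix(rlnorm(20, log(10), 0.5), 5, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  tab <- mini_table(x, c("PC", "PE", "PG", "PI", "PS"))
  x2 <- x; x2[, 2] <- x2[, 2] * 17
  tab2 <- mini_table(x2, c("PC", "PE", "PG", "PI", "PS"))
  expect_equal(normalize_lipids(tab)$intensity,
               normalize_lipids(tab2)$intensity)
})

test_that("transform maps the global minimum to zero and preserves ranks", {
  set.seed(43)
  x <- matrix(rlnorm(24, log(10), 0.5), 6, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  x[6, ] <- 7  # constant lipid
  tab <- mini_table(x, rep("PC", 6), sprintf("PC %d:1", 30 + 1:6))
  tr <- transform_lipids(tab)
  expect_equal(min(tr$intensity), 0)
  expect_equal(attr(tr, "constant_lipids"), "PC 36:1")
  expect_equal(unname(tr$intensity[6, ]),
               rep(log2(attr(tr, "shift_constant")), 4))
  for (i in 1:5)
    expect_equal(rank(tr$intensity[i, ]), rank(x[i, ]))
})

test_that("differential testing: exact equality gives no calls", {
  d <- data.frame(sample_id = paste0("s", 1:8),
                  genotype = rep(c("wildtype", "mutant"), each = 4))
  x <- matrix(rep(rlnorm(6, log(10), 1), 8), 6, 8,
              dimnames = list(NULL, d$sample_id))
  tab <- mini_table(x, c("PC", "PE", "PG", "PI", "PS", "Cer"))
  res <- differential_lipids(tab, d)
  expect_false(any(res$species$significant))
  expect_equal(res$species$log2_fc, rep(0, 6))
})

test_that("class sums conserve species totals and power/type-I calibrate", {
  # conservation invariant
  cfg <- small_cfg(seed = 44)
  lip <- simulate_lipids(cfg)
  m <- normalize_lipids(merge_modes(lip$pos, lip$neg))
  cls <- rowsum(m$intensity, m$meta$class)
  expect_equal(colSums(cls), colSums(m$intensity))

  # type-I proportion at alpha = 0.05 on null lipids, and power at
  # planted |log2FC| = 1, noise CV 0.1, n = 5
  set.seed(45)
  alpha <- 0.05
  res <- lapply(1:60, function(s) {
    cfg <- small_cfg(n_lipids_per_class = 2L, n_diff_lipids = 4L,
                     lipid_fc_log2 = 1, noise_cv = 0.1,
                     n_lipid_replicates = 5L, coupling = FALSE, seed = 400 + s)
    lip <- simulate_lipids(cfg)
    norm <- normalize_lipids(merge_modes(lip$pos, lip$neg))
    dr <- differential_lipids(norm, lip$design)$species
    planted <- dr$lipid_id %in% lip$truth$differential_lipids$lipid_id |
      sub(" \\[(pos|neg)\\]$", "", dr$lipid_id) %in%
        lip$truth$differential_lipids$lipid_id
    c(t1 = mean(dr$significant[!planted]), pw = mean(dr$significant[planted]))
  })
  t1 <- vapply(res, `[[`, numeric(1), "t1")
  pw <- vapply(res, `[[`, numeric(1), "pw")
  mc_se <- sd(t1) / sqrt(length(t1))
  expect_lt(abs(mean(t1) - alpha), 3 * mc_se + 0.01)
  expect_gte(mean(pw), 0.8)
})

test_that("retention-time correction handles identity, offset and curvature", {
  peaks <- data.frame(mz = seq(400, 800, 100), rt = 1:5)
  mk_id <- data.frame(observed_rt = c(1, 5), library_rt = c(1, 5))
  expect_equal(rt_correct(peaks, mk_id)$rt, peaks$rt)
  mk_off <- data.frame(observed_rt = c(2, 6), library_rt = c(1, 5))
  expect_equal(rt_correct(peaks, mk_off)$rt, peaks$rt - 1)
  expect_warning(rt_correct(peaks, mk_id[1, , drop = FALSE]), "fewer than 2")
  # nonlinear drift sampled at 5 markers: residual < 0.05 min
  lib <- data.frame(name = sprintf("l%02d", 1:15), mz = 400 + 1:15 * 30,
                    adduct = "[M+H]+", rt = seq(0.5, 14.5, 1))
  drift <- function(t) t + 0.2 * sin(t / 4) + 0.2
  pk <- simulate_peaks(lib, drift = drift, ppm_jitter = 0,
                       marker_idx = c(1, 4, 8, 11, 15), seed = 9)
  corr <- rt_correct(pk$peaks, pk$markers)
  expect_lt(max(abs(corr$rt - lib$rt)), 0.05)
})

test_that("library matching agrees with the all-pairs oracle and is monotone", {
  set.seed(46)
  for (trial in 1:100) {
    nl <- sample(3:8, 1); np <- sample(3:10, 1)
    lib <- data.frame(name = sprintf("l%02d", seq_len(nl)),
                      mz = runif(nl, 400, 900), adduct = "[M+H]+",
                      rt = runif(nl, 0, 15))
    peaks <- data.frame(
      mz = lib$mz[sample(nl, np, replace = TRUE)] *
        (1 + runif(np, -10, 10) * 1e-6),
      rt = runif(np, 0, 15))
    got <- match_library(peaks, lib)$matches
    ora <- bf_match(peaks, lib)
    expect_equal(got[, c("peak", "name")], ora,
                 ignore_attr = TRUE)
    # shrinking tolerances never adds matches
    tight <- match_library(peaks, lib, ppm_tol = 2, rt_tol = 0.2)$matches
    expect_true(all(paste(tight$peak, tight$name) %in%
                      paste(got$peak, got$name)))
  }
})
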