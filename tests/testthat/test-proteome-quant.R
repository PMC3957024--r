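test_that("presence filter keeps fraction-specific peptides and drops sparse ones", {
  d <- make_design(n_rep = 2)  # 4 samples per fraction across genotypes
  ev <- rbind(
    # seen in 3/4 DRM samples (75%), nothing elsewhere -> retained
    data.frame(peptide_id = "pepA", protein_id = "p1",
               sample_id = d$sample_id[d$fraction == "DRM"][1:3],
               intensity = 1),
    # seen in 2/4 of every fraction (50%) -> removed
    data.frame(peptide_id = "pepB", protein_id = "p2",
               sample_id = d$sample_id[!duplicated(paste(d$genotype, d$fraction))],
               intensity = 1))
  out <- filter_peptides(ev, d)
  expect_setequal(unique(out$peptide_id), "pepA")
  expect_equal(attr(out, "removed")$peptide_id, "pepB")
  expect_equal(attr(out, "removed")$best_presence, 0.5)
  # the strict all-fractions reading removes both
  out_all <- filter_peptides(ev, d, scope = "all_fractions")
  expect_equal(nrow(out_all), 0)
})

test_that("empty evidence yields an explicit empty result", {
  d <- make_design()
  ev <- data.frame(peptide_id = character(0), protein_id = character(0),
                   sample_id = character(0), intensity = numeric(0))
  out <- filter_peptides(ev, d)
  expect_equal(nrow(out), 0)
  expect_s3_class(attr(out, "removed"), "data.frame")
})

test_that("presence filter agrees with the brute-force oracle", {
  d <- make_design(n_rep = 3)
  set.seed(11)
  for (trial in 1:100) {
    ev <- random_evidence(d, n_pep = sample(3:10, 1),
                          p_present = runif(1, 0.3, 0.9))
    got <- sort(unique(filter_peptides(ev, d)$peptide_id))
    expect_identical(got, bf_filter(ev, d))
  }
})

test_that("total-ion normalization produces per-sample fractions", {
  d <- make_design(n_rep = 1, fractions = "DRM", genotypes = "wildtype")
  ev <- data.frame(peptide_id = c("a", "b", "c"), protein_id = "p",
                   sample_id = d$sample_id[1], intensity = c(2, 3, 5))
  out <- normalize_total_ion(ev)
  expect_equal(out$intensity, c(0.2, 0.3, 0.5))
  # single-peptide sample is the identity
  ev1 <- ev[1, ]
  expect_equal(normalize_total_ion(ev1)$intensity, 1)
  # idempotence: renormalizing is a no-op
  expect_equal(normalize_total_ion(out)$intensity, out$intensity)
})

test_that("normalization sums to one and drops all-missing samples", {
  d <- make_design(n_rep = 3)
  set.seed(12)
  ev <- random_evidence(d, n_pep = 12)
  out <- normalize_total_ion(ev)
  sums <- tapply(out$intensity, out$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  ev_bad <- rbind(ev, data.frame(peptide_id = "pepX", protein_id = "px",
                                 sample_id = "ghost", intensity = NA_real_))
  expect_warning(normalize_total_ion(ev_bad), "no quantified")
})

test_that("aggregation: single peptide passes through; offsets cancel", {
  d <- make_design(n_rep = 1, fractions = c("DRM", "DSF", "SP"),
                   genotypes = "wildtype")
  s <- d$sample_id
  one <- data.frame(peptide_id = "a", protein_id = "p", sample_id = s,
                    intensity = c(0.1, 0.2, 0.3))
  pq <- aggregate_protein(one, d)
  expect_equal(unname(pq$abundance["p", s]), c(0.1, 0.2, 0.3))
  # two peptides, identical shape, 10x offset: hand computation
  # scales: median(0.1,0.2,0.3)=0.2 and 2.0; both scaled to (0.5,1,1.5);
  # protein = scaled * median(scales) = (0.5,1,1.5) * 1.1
  two <- rbind(one, data.frame(peptide_id = "b", protein_id = "p",
                               sample_id = s, intensity = c(1, 2, 3)))
  pq2 <- aggregate_protein(two, d)
  expect_equal(unname(pq2$abundance["p", s]), c(0.5, 1, 1.5) * 1.1)
  # permuting row order changes nothing
  pq3 <- aggregate_protein(two[sample(nrow(two)), ], d)
  expect_equal(pq2$abundance, pq3$abundance)
})

test_that("aggregation agrees with the spreadsheet-style oracle", {
  d <- make_design(n_rep = 3)
  set.seed(13)
  for (trial in 1:100) {
    ev <- random_evidence(d, n_pep = sample(3:5, 1), n_prot = 2,
                          p_present = runif(1, 0.5, 1))
    pq <- aggregate_protein(ev, d)
    expect_equal(pq$abundance, bf_aggregate(ev, d))
  }
})

test_that("quantitation is invariant to per-sample intensity scaling", {
  d <- make_design(n_rep = 2)
  set.seed(14)
  ev <- random_evidence(d, n_pep = 10, p_present = 0.8)
  base <- aggregate_protein(normalize_total_ion(filter_peptides(ev, d)), d)
  ev2 <- ev
  ev2$intensity[ev2$sample_id == d$sample_id[1]] <-
    ev2$intensity[ev2$sample_id == d$sample_id[1]] * 37
  scaled <- aggregate_protein(normalize_total_ion(filter_peptides(ev2, d)), d)
  expect_equal(base$abundance, scaled$abundance)
})

test_that("injection averaging collapses technical replicates", {
  d <- make_design(n_rep = 2, fractions = "DRM", genotypes = "wildtype")
  d <- rbind(d, d)
  d$injection <- rep(1:2, each = 2)
  d$sample_id <- paste0(d$sample_id, "_inj", d$injection)
  ev <- data.frame(peptide_id = "a", protein_id = "p",
                   sample_id = d$sample_id,
                   intensity = c(10, 20, 30, 40))
  out <- average_injections(ev, d)
  expect_equal(nrow(out$design), 2)
  expect_setequal(out$evidence$intensity, c(mean(c(10, 30)),
                                            mean(c(20, 40))))
})

test_that("evidence round-trips through the MaxQuant dialect", {
  d <- make_design(n_rep = 2)
  set.seed(15)
  ev <- random_evidence(d, n_pep = 6)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_evidence(ev, path)
  back <- read_evidence(path)
  expect_equal(back$intensity, ev$intensity)
  expect_equal(back$peptide_id, ev$peptide_id)
})
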