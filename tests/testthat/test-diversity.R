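test_that("nucleotide diversity matches hand-computed pairwise values", {
  expect_identical(nucleotide_diversity(c("ACGT", "ACGT")), 0)
  expect_equal(nucleotide_diversity(c("ACGT", "ACGA")), 0.25)
  expect_equal(nucleotide_diversity(c("ACGT", "ACGA", "ACGA")), 1 / 6)
  ## pairwise deletion: gap and N sites are never compared
  expect_equal(nucleotide_diversity(c("AC-T", "ACGA")), 1 / 3)
  expect_equal(nucleotide_diversity(c("ACNT", "ACGA")), 1 / 3)
  ## lower case handled
  expect_equal(nucleotide_diversity(c("acgt", "ACGA")), 0.25)
  expect_error(nucleotide_diversity("ACGT"), "at least 2")
  expect_error(nucleotide_diversity(c("ACGT", "ACG")), "equal length")
})

test_that("nucleotide diversity agrees exactly with a brute-force oracle", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    L <- sample(5:50, 1)
    aln <- random_alignment(n, L)
    oracle <- pi_bruteforce(aln)
    if (is.na(oracle)) {
      expect_error(suppressMessages(nucleotide_diversity(aln)))
    } else {
      expect_identical(suppressMessages(nucleotide_diversity(aln)), oracle)
    }
  }
})

test_that("a pair with no comparable sites is excluded from the pair count", {
  aln <- c("AAAA", "----", "AAAT")
  expect_message(v <- nucleotide_diversity(aln), "no comparable sites")
  ## only the (1,3) pair contributes: 1 mismatch / 4 sites
  expect_equal(v, 0.25)
})

test_that("GDE identities: perfect evenness, single OTU, worked example", {
  expect_equal(gde(c(0.02, 0.02, 0.02)), 1, tolerance = 1e-14)
  expect_equal(gde(0.05), 1, tolerance = 1e-14)
  expect_equal(gde(c(0.01, 0.001, 0, 0)), gde_direct(c(0.01, 0.001, 0, 0)),
               tolerance = 1e-14)
  ## zero-pi OTUs lower GDE through N only
  expect_equal(gde(c(0.02, 0.02, 0, 0)), 2 / 4, tolerance = 1e-14)
  expect_true(is.na(gde(c(0, 0, 0))))
  expect_error(gde(numeric(0)))
  expect_error(gde(c(0.1, -0.01)), "negative")
})

test_that("GDE bounds and equality condition hold on random vectors", {
  set.seed(7)
  for (i in 1:500) {
    N <- sample(1:12, 1)
    pis <- stats::rexp(N, 50) * stats::rbinom(N, 1, 0.8)
    if (all(pis == 0)) next
    g <- gde(pis)
    expect_gte(g, 1 / N - 1e-12)
    expect_lte(g, 1 + 1e-12)
    if (g > 1 - 1e-12) {
      nz <- pis[pis > 0]
      expect_true(length(nz) == N && max(abs(nz - nz[1])) < 1e-12)
    }
  }
})

test_that("GDE never decreases under a mean-preserving contraction", {
  set.seed(8)
  for (i in 1:300) {
    pis <- stats::rexp(3, 50)
    j <- sample(3, 2)
    hi <- which.max(pis[j]); lo <- which.min(pis[j])
    d <- (pis[j[hi]] - pis[j[lo]]) * stats::runif(1, 0, 0.5)
    contracted <- pis
    contracted[j[hi]] <- contracted[j[hi]] - d
    contracted[j[lo]] <- contracted[j[lo]] + d
    expect_gte(gde(contracted), gde(pis) - 1e-12)
  }
})

test_that("literal-formula GDE variant evaluates the unnormalised entropy", {
  pis <- c(0.01, 0.02, 0.03)
  H <- -sum(pis * log(pis))
  expect_equal(gde(pis, normalize = FALSE), exp(H) / 3, tolerance = 1e-14)
})

test_that("GDM is the mean with a square-root transform", {
  expect_equal(gdm(c(0, 0)), list(raw = 0, transformed = 0))
  expect_equal(gdm(0.04), list(raw = 0.04, transformed = 0.2))
  g <- gdm(c(0.01, 0.03))
  expect_equal(g$raw, 0.02)
  expect_equal(g$transformed, sqrt(0.02))
  expect_error(gdm(numeric(0)))
})

test_that("cell summaries drop low-copy OTUs and sparse cells, and match direct recomputation", {
  w <- tiny_world()
  ca <- assign_cell(w$records$lat, w$records$lon, w$grid)
  recs <- cbind(w$records, ca)
  s <- summarize_cells(recs, min_otus = 10, min_copies = 3)
  expect_equal(nrow(s), 6)  # all cells have 12 OTUs x 3 copies
  ## direct recomputation from the emitted alignments
  for (cl in s$cell) {
    keys <- grep(paste0("^", cl, "__"), names(w$alignments), value = TRUE)
    pis <- vapply(keys, function(k) pi_bruteforce(w$alignments[[k]]), numeric(1))
    expect_equal(s$gdm_raw[s$cell == cl], mean(pis), tolerance = 1e-12)
    expect_equal(s$gdm[s$cell == cl], sqrt(mean(pis)), tolerance = 1e-12)
    expect_equal(s$gde[s$cell == cl], gde_direct(pis), tolerance = 1e-12)
  }
  ## a 2-copy OTU is excluded from the diversity set
  recs2 <- recs[-1, ]  # first OTU of first cell now has 2 copies
  s2 <- summarize_cells(recs2, min_otus = 10, min_copies = 3)
  od2 <- attr(s2, "otu_diversity")
  dropped_otu <- recs$bin_uri[1]
  cl1 <- recs$cell[1]
  expect_false(any(od2$otu_id == dropped_otu & od2$cell == cl1))
  expect_equal(s2$n_otus[s2$cell == cl1], 11)
  ## sparse cells are dropped under a higher threshold
  s3 <- summarize_cells(recs, min_otus = 25)
  expect_equal(nrow(s3), 0)
})

test_that("cell metrics are invariant to record order", {
  w <- tiny_world(seed = 9)
  ca <- assign_cell(w$records$lat, w$records$lon, w$grid)
  recs <- cbind(w$records, ca)
  s1 <- summarize_cells(recs, min_otus = 10)
  set.seed(1)
  perm <- sample(nrow(recs))
  s2 <- summarize_cells(recs[perm, ], min_otus = 10)
  s2 <- s2[match(s1$cell, s2$cell), ]
  expect_equal(s1$gdm, s2$gdm, tolerance = 1e-14)
  expect_equal(s1$gde, s2$gde, tolerance = 1e-14)
})

test_that("order-subset comparison recovers a planted order effect and a no-op is exact", {
  w <- generate_world(world_spec(n_rows = 2, n_cols = 3, otus_per_cell = 25,
                                 samples_per_otu = 3,
                                 order_theta_mult = c(Diptera = 6)),
                      seed = 31)
  ca <- assign_cell(w$records$lat, w$records$lon, w$grid)
  recs <- cbind(w$records, ca)
  cmp <- order_subset_comparison(recs, "Diptera", min_otus = 10)
  ## removing the hot order lowers GDM: full - subset > 0
  diff_gdm <- cmp$tests$mean_diff[cmp$tests$metric == "gdm"]
  expect_gt(diff_gdm, 0)
  none <- order_subset_comparison(recs, character(0), min_otus = 10)
  expect_equal(none$tests$mean_diff, c(0, 0))
  expect_equal(none$tests$p, c(1, 1))
})

test_that("cell bootstrap is consistent and reproducible", {
  expect_equal(unique(resample_cell(rep(0.03, 8), 50, 100, seed = 1)$gde), 1)
  pis <- stats::rexp(60, 40)
  rs1 <- resample_cell(pis, n_otus_draw = 100, n_resamples = 500, seed = 3)
  rs2 <- resample_cell(pis, n_otus_draw = 100, n_resamples = 500, seed = 3)
  expect_identical(rs1, rs2)
  se <- stats::sd(rs1$gdm_raw)
  expect_lt(abs(mean(rs1$gdm_raw) - mean(pis)), 3 * se)
})

test_that("occupancy distribution counts cells per OTU and conserves totals", {
  w <- generate_world(world_spec(n_rows = 2, n_cols = 3, otus_per_cell = 8,
                                 samples_per_otu = 3,
                                 multicell_otus = 2, multicell_span = 3),
                      seed = 5)
  ca <- assign_cell(w$records$lat, w$records$lon, w$grid)
  recs <- cbind(w$records, ca)
  occ <- occupancy_table(recs)
  expect_equal(sum(occ$histogram), nrow(occ$per_otu))
  for (mc in names(w$truth$multicell)) {
    expect_equal(occ$per_otu$n_cells[occ$per_otu$otu_id == mc],
                 length(w$truth$multicell[[mc]]))
  }
  single <- occ$per_otu$otu_id[!grepl("MC", occ$per_otu$otu_id)][1]
  expect_equal(occ$per_otu$n_cells[occ$per_otu$otu_id == single], 1)
})
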