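test_that("record TSV round-trips with missing coordinates preserved", {
  d <- make_records(3)
  d$lat[2] <- NA; d$lon[2] <- NA
  d$nucleotides[3] <- tolower(d$nucleotides[3])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(d, path)
  r <- read_records(path)
  expect_equal(nrow(r), 3)
  expect_true(is.na(r$lat[2]))
  expect_identical(r$nucleotides[3], toupper(d$nucleotides[3]))
  expect_identical(r$processid, d$processid)
})

test_that("malformed rows are skipped with a count; missing columns are fatal", {
  d <- make_records(4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_records(d, path)
  lines <- readLines(path)
  lines[3] <- sub("^REC2", "", lines[3])  # drop the record id
  writeLines(lines, path)
  expect_message(r <- read_records(path), "skipped 1 malformed")
  expect_equal(nrow(r), 3)
  expect_equal(attr(r, "n_malformed"), 1L)

  d2 <- d[, setdiff(names(d), "bin_uri")]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(d2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_records(path2), "bin_uri")
})

test_that("end-gap trimming removes only leading/trailing gap runs", {
  expect_identical(trim_end_gaps("--ACGT--"), "ACGT")
  expect_identical(trim_end_gaps("AC--GT"), "AC--GT")
  expect_identical(trim_end_gaps("------"), "")
  expect_identical(trim_end_gaps(c("-A-", "AC")), c("A", "AC"))
})

test_that("length filter uses strict removal inequalities on ungapped trimmed length", {
  mk <- function(len, pad_gaps = 0) {
    d <- make_records(1, seq_len_bp = len)
    d$processid <- paste0("LEN", len, "_", pad_gaps)
    if (pad_gaps > 0)
      d$nucleotides <- paste0(strrep("-", pad_gaps), d$nucleotides, strrep("-", pad_gaps))
    d
  }
  res <- apply_filters(rbind(mk(801), mk(800), mk(400), mk(399)))
  expect_equal(res$report$too_long, 1)
  expect_equal(res$report$too_short, 1)
  expect_equal(res$report$retained, 2)
  expect_setequal(ungapped_length(res$records$nucleotides), c(800, 400))
  ## interior gaps do not count toward length; end gaps are trimmed first
  d <- mk(395, pad_gaps = 10)
  d$nucleotides <- paste0(substr(d$nucleotides, 1, 200), "------",
                          substr(d$nucleotides, 201, nchar(d$nucleotides)))
  res2 <- apply_filters(d)
  expect_equal(res2$report$too_short, 1)
})

test_that("invasive removal requires list membership AND >= 2 continents", {
  a <- make_records(3, continent = "ContinentA")
  a$species_name <- "Invasivus exemplum"
  b <- make_records(3, continent = "ContinentB")
  b$processid <- paste0(b$processid, "b")
  b$species_name <- "Invasivus exemplum"
  c1 <- make_records(3, continent = "ContinentA", otu = "BOLD:BBB0002")
  c1$processid <- paste0(c1$processid, "c")
  c1$species_name <- "Localis tantum"   # listed but single-continent
  recs <- rbind(a, b, c1)
  res <- apply_filters(recs, invasive_list = c("Invasivus exemplum", "Localis tantum"))
  expect_equal(res$report$invasive, 6)
  expect_equal(res$report$retained, 3)
  expect_true(all(res$records$species_name == "Localis tantum"))
  ## no list: nothing removed
  res2 <- apply_filters(recs)
  expect_equal(res2$report$retained, 9)
})

test_that("filter report reconciles and the retained set is order-independent", {
  w <- inject_pathologies(tiny_world(seed = 3))
  res <- apply_filters(w$records, invasive_list = w$truth$pathology$invasive_list)
  rep <- res$report
  expect_equal(rep$retained + rep$duplicate_record + rep$too_long + rep$too_short +
                 rep$ungeoreferenced + rep$invasive, rep$n_input)
  ## conjunctive rules: shuffling input order preserves the retained set
  set.seed(2)
  perm <- sample(nrow(w$records))
  res2 <- apply_filters(w$records[perm, ], invasive_list = w$truth$pathology$invasive_list)
  expect_setequal(res2$records$processid, res$records$processid)
})

test_that("duplicate record ids are dropped keeping the first occurrence", {
  d <- make_records(3)
  d2 <- rbind(d, d[2, ])
  res <- apply_filters(d2)
  expect_equal(res$report$duplicate_record, 1)
  expect_equal(res$report$retained, 3)
})

test_that("FASTA writer/reader round-trips aligned sequences", {
  seqs <- c(s1 = "ACGTACGTAC", s2 = "ACGTAGGTAC", s3 = "ACG-ACGTAC")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_seqs(seqs, path)
  back <- read_fasta_seqs(path)
  expect_identical(unname(back), unname(seqs))
  expect_identical(names(back), names(seqs))
})
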