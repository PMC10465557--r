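## Reading BOLD-schema specimen tables and FASTA, and the record-level
## quality filters applied before any diversity calculation.

.BOLD_COLS <- c("processid", "bin_uri", "order_name", "species_name",
                "lat", "lon", "country", "continent", "nucleotides")

#' Read a BOLD-schema specimen table
#'
#' Tab-separated with a header row and the columns `processid`, `bin_uri`,
#' `order_name`, `species_name`, `lat`, `lon`, `country`, `continent`,
#' `nucleotides`. Missing coordinates are preserved as `NA` (never coerced
#' to zero); sequences are upper-cased. Rows lacking a record id or a
#' sequence are logged and skipped; a missing mandatory column is a hard
#' error.
#'
#' @param path path to the TSV file.
#' @return data.frame of records; attribute `n_malformed` counts skipped rows.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = c("", "NA"), quote = "")
  missing_cols <- setdiff(.BOLD_COLS, names(d))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  d <- d[, .BOLD_COLS]
  bad <- is.na(d$processid) | is.na(d$nucleotides)
  if (any(bad)) {
    message(sprintf("read_records: skipped %d malformed row(s)", sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  d$lat <- suppressWarnings(as.numeric(d$lat))
  d$lon <- suppressWarnings(as.numeric(d$lon))
  if (any(d$lat < -90 | d$lat > 90, na.rm = TRUE) ||
      any(d$lon < -180 | d$lon > 180, na.rm = TRUE))
    stop("coordinates outside WGS84 bounds")
  d$nucleotides <- toupper(d$nucleotides)
  rownames(d) <- NULL
  attr(d, "n_malformed") <- sum(bad)
  d
}

#' Write records as a BOLD-schema TSV
#' @param records data.frame with the BOLD columns.
#' @param path output path.
#' @export
write_records <- function(records, path) {
  utils::write.table(records[, .BOLD_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Trim end gaps from an aligned sequence
#'
#' Removes leading and trailing runs of `-`; interior gaps are untouched.
#' An all-gap sequence becomes empty (and then fails the length filter).
#'
#' @param sequence character vector of IUPAC strings.
#' @return trimmed character vector.
#' @export
#' @examples
#' trim_end_gaps("--ACGT--")  # "ACGT"
#' trim_end_gaps("AC--GT")    # unchanged
trim_end_gaps <- function(sequence) {
  sub("-+$", "", sub("^-+", "", sequence))
}

## Ungapped length: non-gap characters of the trimmed sequence. 'N' and other
## ambiguity codes count as (ambiguous) bases, consistent with alignment
## practice; only '-' is a gap.
ungapped_length <- function(sequence) {
  nchar(gsub("-", "", trim_end_gaps(sequence), fixed = TRUE))
}

#' Read a two-column invasive-taxon list
#'
#' CSV with columns `taxon` (species name or OTU/BIN id) and `source`.
#' @param path CSV path.
#' @return character vector of taxa.
#' @export
read_invasive_list <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"taxon" %in% names(d)) stop("invasive list needs a 'taxon' column")
  unique(d$taxon)
}

#' Apply the record-level quality filters
#'
#' Retains records whose trimmed, ungapped sequence length lies in
#' `[min_len, max_len]` (removal inequalities are strict: >800 bp and
#' <400 bp go, the boundary values stay), that carry coordinates, and that
#' do not belong to a listed invasive taxon observed on two or more
#' continents in the data. Duplicated record ids are dropped first (first
#' occurrence kept). The rules are conjunctive, so the retained set does not
#' depend on application order; for reporting, each removed record is
#' attributed to the first matching rule in the order duplicate_record,
#' too_long, too_short, ungeoreferenced, invasive.
#'
#' @param records data.frame as from [read_records()].
#' @param invasive_list character vector of species names and/or OTU ids
#'   flagged as invasive (membership is necessary but not sufficient:
#'   removal also requires presence on >= 2 continents).
#' @param min_len,max_len retained ungapped length bounds (default 400, 800).
#' @return list with `records` (retained, sequences end-trimmed) and
#'   `report`, a one-row data.frame reconciling counts.
#' @export
apply_filters <- function(records, invasive_list = character(),
                          min_len = 400, max_len = 800) {
  n_input <- nrow(records)
  records$nucleotides <- trim_end_gaps(records$nucleotides)
  len <- ungapped_length(records$nucleotides)

  dup <- duplicated(records$processid)
  too_long <- len > max_len
  too_short <- len < min_len
  ungeo <- is.na(records$lat) | is.na(records$lon)

  ## trans-continental invasive taxa: on the list AND seen on >= 2 continents
  invasive <- rep(FALSE, n_input)
  if (length(invasive_list)) {
    for (field in c("species_name", "bin_uri")) {
      v <- records[[field]]
      flagged <- !is.na(v) & v %in% invasive_list
      if (!any(flagged)) next
      n_cont <- tapply(records$continent[flagged], v[flagged],
                       function(z) length(unique(z[!is.na(z)])))
      multi <- names(n_cont)[n_cont >= 2]
      invasive <- invasive | (flagged & v %in% multi)
    }
  }

  remove_any <- dup | too_long | too_short | ungeo | invasive
  ## first-matching-rule attribution
  attr_dup <- dup
  attr_long <- too_long & !attr_dup
  attr_short <- too_short & !attr_dup & !attr_long
  attr_ungeo <- ungeo & !attr_dup & !attr_long & !attr_short
  attr_inv <- invasive & !attr_dup & !attr_long & !attr_short & !attr_ungeo

  report <- data.frame(n_input = n_input,
                       duplicate_record = sum(attr_dup),
                       too_long = sum(attr_long),
                       too_short = sum(attr_short),
                       ungeoreferenced = sum(attr_ungeo),
                       invasive = sum(attr_inv),
                       retained = sum(!remove_any))
  out <- records[!remove_any, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' Read an aligned FASTA file as a character vector of sequences
#' @param path FASTA path.
#' @return named character vector (upper case).
#' @export
read_fasta_seqs <- function(path) {
  d <- ape::read.dna(path, format = "fasta", as.character = TRUE, as.matrix = FALSE)
  vapply(d, function(s) toupper(paste(s, collapse = "")), character(1))
}

#' Write sequences to FASTA (80-column wrap)
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  mat <- lapply(seqs, function(s) strsplit(tolower(s), "")[[1]])
  ape::write.dna(mat, path, format = "fasta", colsep = "", nbcol = -1, colw = 80)
  invisible(path)
}
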