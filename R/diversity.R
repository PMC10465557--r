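## Per-OTU nucleotide diversity and its per-cell aggregates: the genetic
## diversity mean (GDM) and genetic diversity evenness (GDE).

## Map sequences (character vector of equal-length strings, or a character
## matrix with one row per sequence) to an integer matrix: A,C,G,T -> 1..4,
## everything else (gaps, ambiguity codes) -> NA. Case-insensitive.
seq_matrix <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- toupper(seqs)
  } else {
    seqs <- toupper(as.character(seqs))
    L <- unique(nchar(seqs))
    if (length(L) != 1)
      stop("sequences must be aligned (equal length)")
    m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  }
  out <- matrix(NA_integer_, nrow(m), ncol(m))
  out[m == "A"] <- 1L; out[m == "C"] <- 2L
  out[m == "G"] <- 3L; out[m == "T"] <- 4L
  out
}

#' Nucleotide diversity of an alignment
#'
#' Mean over all unordered sequence pairs of (mismatches / sites compared).
#' A site enters a pair's comparison only when both sequences carry an
#' unambiguous base (A, C, G or T) there: gaps and IUPAC ambiguity codes are
#' handled by pairwise deletion and never count as matches or mismatches.
#' Each pair is normalised by its own number of comparable sites, since
#' trimmed barcode sequences vary in coverage. A pair with zero comparable
#' sites contributes nothing and is dropped from the pair count (a message is
#' emitted).
#'
#' @param alignment character vector of equal-length sequences, a character
#'   matrix (rows = sequences), or an integer matrix as produced internally.
#' @return nucleotide diversity per site (pi), in `[0, 1]`.
#' @export
#' @examples
#' nucleotide_diversity(c("ACGT", "ACGA"))          # 0.25
#' nucleotide_diversity(c("ACGT", "ACGA", "ACGA"))  # 1/6
nucleotide_diversity <- function(alignment) {
  m <- if (is.matrix(alignment) && is.integer(alignment)) alignment
       else seq_matrix(alignment)
  n <- nrow(m)
  if (n < 2) stop("nucleotide diversity needs at least 2 sequences")
  tot <- 0
  npairs <- 0L
  dropped <- 0L
  for (i in seq_len(n - 1)) {
    a <- m[i, ]
    for (j in (i + 1):n) {
      b <- m[j, ]
      ok <- !is.na(a) & !is.na(b)
      comp <- sum(ok)
      if (comp == 0L) { dropped <- dropped + 1L; next }
      tot <- tot + sum(a[ok] != b[ok]) / comp
      npairs <- npairs + 1L
    }
  }
  if (dropped > 0L)
    message(sprintf("nucleotide_diversity: %d pair(s) with no comparable sites excluded", dropped))
  if (npairs == 0L) stop("no sequence pair had comparable sites")
  tot / npairs
}

#' Genetic diversity evenness (GDE) of a set of per-OTU diversities
#'
#' First-order Hill number of the per-OTU nucleotide diversities divided by
#' OTU richness N. By default the diversities are normalised to proportions
#' `p_i = pi_i / sum(pi)` before the Shannon entropy, the Hill-number reading
#' under which the richness correction bounds the result in `[1/N, 1]`; OTUs
#' with `pi = 0` contribute `0 * log(0) = 0` (they lower GDE through N but
#' not through the entropy). `normalize = FALSE` evaluates the literal
#' unnormalised form `exp(sum(-pi * log(pi))) / N` for comparison; no claim
#' is made that either variant matches any particular archived result.
#'
#' @param pi_values non-negative numeric vector, one value per OTU.
#' @param normalize normalise to proportions first (default TRUE).
#' @return GDE in `(0, 1]` (normalised form), or `NA` when every value is
#'   zero, in which case evenness is undefined and the caller must flag the
#'   cell rather than treat it as 0.
#' @export
#' @examples
#' gde(c(0.02, 0.02, 0.02))   # 1: perfect evenness
#' gde(c(0.01, 0.001, 0, 0))  # ~ 0.339
gde <- function(pi_values, normalize = TRUE) {
  if (length(pi_values) < 1) stop("need at least one OTU")
  if (any(pi_values < 0)) stop("negative diversity value")
  N <- length(pi_values)
  if (all(pi_values == 0)) return(NA_real_)
  v <- if (normalize) pi_values / sum(pi_values) else pi_values
  pos <- v > 0
  H <- -sum(v[pos] * log(v[pos]))
  exp(H) / N
}

#' Genetic diversity mean (GDM)
#'
#' Arithmetic mean of per-OTU nucleotide diversities, plus its square-root
#' transform. The cell-level distribution of raw GDM is strongly
#' right-skewed, so all downstream statistics and modelling use the
#' transformed value; the raw mean is always retained.
#'
#' @param pi_values non-negative numeric vector, one value per OTU.
#' @return list with `raw` (mean) and `transformed` (sqrt of mean).
#' @export
gdm <- function(pi_values) {
  if (length(pi_values) < 1) stop("need at least one OTU")
  m <- mean(pi_values)
  list(raw = m, transformed = sqrt(m))
}

#' Per-OTU diversity within cells
#'
#' Groups cell-assigned records by (cell, OTU), drops OTU-cell groups with
#' fewer than `min_copies` sequences, and computes nucleotide diversity for
#' each remaining group.
#'
#' @param records data.frame with at least `cell`, `otu_id`, `order_name`,
#'   `nucleotides` columns (filtered, cell-assigned).
#' @param min_copies minimum allele copies per OTU per cell (default 3).
#' @return data.frame: cell, otu_id, order_name, n_copies, pi.
#' @export
otu_diversity <- function(records, min_copies = 3) {
  if (is.null(records$otu_id)) records$otu_id <- records$bin_uri
  key <- paste(records$cell, records$otu_id, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  keep <- groups[lengths(groups) >= min_copies]
  if (length(keep) == 0)
    return(data.frame(cell = character(), otu_id = character(),
                      order_name = character(), n_copies = integer(),
                      pi = numeric(), stringsAsFactors = FALSE))
  res <- lapply(keep, function(idx) {
    seqs <- records$nucleotides[idx]
    ## groups are aligned per OTU per cell; unequal lengths are padded is not
    ## expected here -- synthetic alignments are equal length by construction
    data.frame(cell = records$cell[idx[1]],
               otu_id = records$otu_id[idx[1]],
               order_name = records$order_name[idx[1]],
               n_copies = length(idx),
               pi = nucleotide_diversity(seqs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise genetic diversity per grid cell
#'
#' Applies the per-OTU copy threshold, drops cells with fewer than `min_otus`
#' retained OTUs, and computes per-cell GDM (raw and sqrt-transformed), GDE,
#' and sampling counts. Cells where every OTU has zero diversity get
#' `gde = NA` and are counted in the `n_gde_missing` attribute rather than
#' silently assigned a value.
#'
#' @param records filtered, cell-assigned records (see [otu_diversity()]).
#' @param min_otus minimum OTU richness per retained cell; the analysis
#'   threshold menu is 10, 25, 50, 100, 150, 200.
#' @param min_copies minimum allele copies per OTU per cell (default 3).
#' @param gde_normalize passed to [gde()].
#' @return data.frame: cell, n_otus, n_individuals, n_orders, gdm_raw, gdm,
#'   gde. Attribute `otu_diversity` holds the per-OTU table.
#' @export
summarize_cells <- function(records, min_otus = 100, min_copies = 3,
                            gde_normalize = TRUE) {
  od <- otu_diversity(records, min_copies = min_copies)
  if (nrow(od) == 0) {
    out <- data.frame(cell = character(), n_otus = integer(),
                      n_individuals = integer(), n_orders = integer(),
                      gdm_raw = numeric(), gdm = numeric(), gde = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "otu_diversity") <- od
    return(out)
  }
  cells <- split(od, od$cell)
  cells <- cells[vapply(cells, nrow, 1L) >= min_otus]
  if (length(cells) == 0) {
    out <- data.frame(cell = character(), n_otus = integer(),
                      n_individuals = integer(), n_orders = integer(),
                      gdm_raw = numeric(), gdm = numeric(), gde = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "otu_diversity") <- od[0, , drop = FALSE]
    attr(out, "n_gde_missing") <- 0L
    return(out)
  }
  rows <- lapply(cells, function(d) {
    g <- gdm(d$pi)
    data.frame(cell = d$cell[1],
               n_otus = nrow(d),
               n_individuals = sum(d$n_copies),
               n_orders = length(unique(d$order_name)),
               gdm_raw = g$raw, gdm = g$transformed,
               gde = gde(d$pi, normalize = gde_normalize),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_missing <- sum(is.na(out$gde))
  if (n_missing > 0)
    message(sprintf("summarize_cells: %d cell(s) with undefined GDE (all pi = 0)", n_missing))
  attr(out, "otu_diversity") <- od[od$cell %in% out$cell, , drop = FALSE]
  attr(out, "n_gde_missing") <- n_missing
  out
}

#' Effect of removing taxonomic orders on cell-level diversity
#'
#' Recomputes the per-cell summaries with the named orders removed (same
#' thresholds) and compares the resulting per-cell GDM and GDE distributions
#' to the full-data summaries with Welch's unequal-variance t-tests.
#'
#' @param records filtered, cell-assigned records.
#' @param orders_to_remove character vector of `order_name` values.
#' @param min_otus,min_copies thresholds as in [summarize_cells()].
#' @return list with `full` and `subset` summary tables and `tests`, a
#'   data.frame of Welch results (metric, mean_diff, t, df, p).
#' @export
order_subset_comparison <- function(records, orders_to_remove,
                                    min_otus = 100, min_copies = 3) {
  full <- summarize_cells(records, min_otus = min_otus, min_copies = min_copies)
  sub_records <- records[!(records$order_name %in% orders_to_remove), , drop = FALSE]
  subset <- summarize_cells(sub_records, min_otus = min_otus, min_copies = min_copies)
  if (nrow(subset) < 2) stop("order removal leaves fewer than 2 cells")
  one <- function(metric) {
    x <- full[[metric]]; y <- subset[[metric]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (identical(sort(x), sort(y))) {
      ## degenerate no-op removal: identical distributions
      return(data.frame(metric = metric, mean_diff = 0, t = 0,
                        df = length(x) + length(y) - 2, p = 1))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(metric = metric, mean_diff = mean(x) - mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }
  tests <- rbind(one("gdm"), one("gde"))
  rownames(tests) <- NULL
  list(full = full, subset = subset, tests = tests)
}

#' Bootstrap sampling distribution of a cell's GDM and GDE
#'
#' Resamples OTUs within one cell with replacement (`n_otus_draw` per
#' resample) and recomputes both metrics, characterising the sampling
#' variance of heavily sampled cells.
#'
#' @param pi_values per-OTU diversities of one cell.
#' @param n_otus_draw OTUs per resample (default 100).
#' @param n_resamples number of bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return data.frame with columns `gdm` (sqrt scale), `gdm_raw` and `gde`.
#' @export
resample_cell <- function(pi_values, n_otus_draw = 100, n_resamples = 1000,
                          seed = NULL) {
  if (length(pi_values) < 1) stop("cell has no OTUs")
  if (!is.null(seed)) set.seed(seed)
  res <- vapply(seq_len(n_resamples), function(i) {
    draw <- sample(pi_values, n_otus_draw, replace = TRUE)
    c(mean(draw), gde(draw))
  }, numeric(2))
  data.frame(gdm_raw = res[1, ], gdm = sqrt(res[1, ]), gde = res[2, ])
}

#' Grid-cell occupancy distribution of OTUs
#'
#' @param records cell-assigned records.
#' @return list: `per_otu` (data.frame otu_id, n_cells) and `histogram`
#'   (table of the number of OTUs occupying 1, 2, ... cells), plus
#'   `prop_single`, the fraction of OTUs confined to a single cell.
#' @export
occupancy_table <- function(records) {
  if (is.null(records$otu_id)) records$otu_id <- records$bin_uri
  per <- tapply(records$cell, records$otu_id, function(z) length(unique(z)))
  per_otu <- data.frame(otu_id = names(per), n_cells = as.integer(per),
                        stringsAsFactors = FALSE)
  hist <- table(per_otu$n_cells)
  list(per_otu = per_otu, histogram = hist,
       prop_single = mean(per_otu$n_cells == 1))
}
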