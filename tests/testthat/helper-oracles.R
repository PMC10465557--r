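## Independent oracles used across tests. These deliberately share no code
## with the package internals: brute-force double loops and direct formula
## evaluations only.

## Brute-force nucleotide diversity: per pair, loop over sites character by
## character; only A/C/G/T at both positions are comparable.
pi_bruteforce <- function(seqs) {
  seqs <- toupper(seqs)
  n <- length(seqs)
  chars <- strsplit(seqs, "")
  valid <- c("A", "C", "G", "T")
  tot <- 0
  np <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- chars[[i]]; b <- chars[[j]]
      comp <- 0; mm <- 0
      for (s in seq_along(a)) {
        if (a[s] %in% valid && b[s] %in% valid) {
          comp <- comp + 1
          if (a[s] != b[s]) mm <- mm + 1
        }
      }
      if (comp > 0) {
        tot <- tot + mm / comp
        np <- np + 1
      }
    }
  }
  if (np == 0) return(NA_real_)
  tot / np
}

## Random alignment with gaps and ambiguity codes mixed in.
random_alignment <- function(n, L, p_gap = 0.05, p_amb = 0.05) {
  alphabet <- c("A", "C", "G", "T")
  amb <- c("N", "R", "Y", "W")
  vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, L, replace = TRUE)
    k <- stats::rbinom(1, L, p_gap)
    if (k > 0) ch[sample(L, k)] <- "-"
    k <- stats::rbinom(1, L, p_amb)
    if (k > 0) ch[sample(L, k)] <- sample(amb, k, replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
}

## Direct evaluation of the richness-corrected first-order Hill evenness.
gde_direct <- function(pis) {
  p <- pis / sum(pis)
  p <- p[p > 0]
  exp(-sum(p * log(p))) / length(pis)
}

## Spherical area of a lat/lon quadrilateral on the authalic sphere (m^2):
## R^2 * dlon * (sin lat2 - sin lat1).
spherical_quad_area <- function(lat1, lat2, lon1, lon2, R = 6371007.181) {
  R^2 * abs(lon2 - lon1) * pi / 180 * abs(sin(lat2 * pi / 180) - sin(lat1 * pi / 180))
}

## Small clean BOLD-style record table used by the io tests.
make_records <- function(n = 6, seq_len_bp = 600, continent = "ContinentA",
                         otu = "BOLD:AAA0001", lat = 10, lon = 20) {
  data.frame(
    processid = paste0("REC", seq_len(n)),
    bin_uri = otu,
    order_name = "Diptera",
    species_name = "Examplea species",
    lat = lat, lon = lon,
    country = continent, continent = continent,
    nucleotides = vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), seq_len_bp, replace = TRUE), collapse = ""),
      character(1)),
    stringsAsFactors = FALSE)
}

## A tiny world shared by several test files (kept small for speed).
tiny_world <- function(seed = 42, ...) {
  generate_world(world_spec(n_rows = 2, n_cols = 3, otus_per_cell = 12,
                            samples_per_otu = 3, ...), seed = seed)
}
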