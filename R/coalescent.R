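## Hudson single-population neutral coalescent with finite-sites Jukes-Cantor
## mutation, written directly (exponential coalescence intervals, Poisson
## mutation counts on branch lengths) so the sampling experiments are
## self-contained and reproducible.

#' Parameters of a single-population coalescent simulation
#'
#' @param n_samples number of allele copies sampled (>= 2).
#' @param Ne haploid effective population size (> 0). For mitochondrial data
#'   this is the effective number of transmitting lineages.
#' @param mu per-site per-generation mutation rate (> 0 unless a mutation-free
#'   control is wanted; `mu = 0` is allowed and yields identical sequences).
#' @param seq_length alignment length in bp (> 0).
#' @return a `coalescent_params` list.
#' @export
coalescent_params <- function(n_samples, Ne, mu, seq_length) {
  stopifnot(n_samples >= 2, Ne > 0, mu >= 0, seq_length > 0)
  structure(list(n_samples = as.integer(n_samples), Ne = Ne, mu = mu,
                 seq_length = as.integer(seq_length)),
            class = "coalescent_params")
}

## Simulate the genealogy: returns parent pointers and branch lengths (in
## generations) for a Kingman coalescent with pairwise coalescence rate
## choose(k,2)/Ne, i.e. E[pairwise TMRCA] = Ne generations and expected
## pairwise diversity 2*Ne*mu per site.
sim_genealogy <- function(n, Ne) {
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  t_node <- numeric(n_nodes)          # node ages in generations
  active <- seq_len(n)
  nxt <- n + 1L
  t_now <- 0
  while (length(active) > 1) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k * (k - 1) / 2 / Ne)
    pair <- sample(k, 2)
    a <- active[pair[1]]; b <- active[pair[2]]
    parent[a] <- nxt; parent[b] <- nxt
    t_node[nxt] <- t_now
    active <- c(active[-pair], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, age = t_node, n_tips = n, root = n_nodes)
}

#' Simulate an aligned sequence sample under the neutral coalescent
#'
#' Draws a Kingman genealogy for `n_samples` lineages, places
#' `Poisson(mu * L * branch_length)` mutations on each branch, and applies
#' Jukes-Cantor substitution (uniformly chosen site, uniformly chosen
#' different base) down the tree from a uniform random root sequence. A
#' finite-sites model is used deliberately: diversity is then computed from
#' sequence mismatches exactly as the analysis pipeline computes it, and
#' repeat hits at high `theta` are accepted (they bias pi below `theta`
#' only when `theta` per site is large).
#'
#' @param params a [coalescent_params()] object.
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @return character vector of `n_samples` equal-length DNA strings.
#' @export
#' @examples
#' p <- coalescent_params(5, Ne = 1e4, mu = 1e-7, seq_length = 100)
#' sim_coalescent_alignment(p, seed = 1)
sim_coalescent_alignment <- function(params, seed = NULL) {
  stopifnot(inherits(params, "coalescent_params"))
  if (!is.null(seed)) set.seed(seed)
  m <- sim_coalescent_matrix(params)
  apply(matrix(c("A", "C", "G", "T")[m], nrow(m), ncol(m)), 1, paste, collapse = "")
}

## Integer-matrix fast path (rows = sequences, entries 1..4) used by the
## calibration and bias experiments, which evaluate pi on thousands of
## replicates.
sim_coalescent_matrix <- function(params) {
  n <- params$n_samples; L <- params$seq_length
  g <- sim_genealogy(n, params$Ne)
  n_nodes <- 2L * n - 1L
  root_seq <- sample.int(4L, L, replace = TRUE)
  seqs <- matrix(NA_integer_, n, L)
  ## children lists for a preorder walk from the root
  kids <- vector("list", n_nodes)
  for (v in seq_len(n_nodes - 1L)) kids[[g$parent[v]]] <- c(kids[[g$parent[v]]], v)
  stack <- g$root
  node_seq <- vector("list", n_nodes)
  node_seq[[g$root]] <- root_seq
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    s <- node_seq[[v]]
    for (ch in kids[[v]]) {
      bl <- g$age[v] - g$age[ch]
      cs <- s
      ## Jukes-Cantor with Poisson(mu * bl) mutations per site: a site hit
      ## k >= 1 times keeps its base with probability 1/4 + (3/4)(-1/3)^k
      ## (the k-step chain collapsed in closed form), otherwise moves
      ## uniformly to one of the other three bases. Exactly equivalent to
      ## placing the mutations sequentially, but O(L) at any theta.
      k_site <- stats::rpois(L, params$mu * bl)
      hit <- which(k_site > 0L)
      if (length(hit)) {
        p_same <- 0.25 + 0.75 * (-1 / 3)^k_site[hit]
        moves <- hit[stats::runif(length(hit)) > p_same]
        if (length(moves))
          cs[moves] <- (cs[moves] - 1L +
                          sample.int(3L, length(moves), replace = TRUE)) %% 4L + 1L
      }
      if (ch <= n) seqs[ch, ] <- cs else node_seq[[ch]] <- cs
      if (ch > n) stack <- c(stack, ch)
    }
    node_seq[v] <- list(NULL)
  }
  seqs
}

#' Duplicate-allele bias experiment
#'
#' BOLD submissions may omit duplicate alleles, so field datasets can contain
#' only unique haplotypes per specimen batch. This experiment quantifies the
#' resulting bias: for each effective population size in `ne_grid` it
#' simulates `n_reps` coalescent samples (fixed `mu`, `n_samples`,
#' `seq_length`, so `theta = 2 * Ne * mu` grows with Ne), computes nucleotide
#' diversity on all copies and again after collapsing to unique haplotypes
#' (exact string equality after upper-casing), and reports per-Ne means and
#' standard errors of both, plus the bias (unique minus all).
#'
#' The default mutation rate is a designed experimental scale, not a
#' biological estimate: it is chosen so that the Ne grid
#' `{1e3, 1e4, 1e5, 1e6}` spans the duplicate-dominated regime
#' (`theta * L` of order 10^2 at the low end) through to the regime where
#' every sampled copy is a unique haplotype (`theta * L` far above
#' `n_samples^2`), which is where the bias converges to zero. On average the
#' bias is positive -- removing duplicates discards the zero-distance pairs
#' created by recent coalescences -- but individual replicates can have
#' negative bias when the duplicated haplotype sits on a long branch, since
#' duplication also up-weights that haplotype's long-distance pairs.
#'
#' When a replicate collapses to a single haplotype its unique-only diversity
#' is recorded as 0 (the single-sequence rule: no pairs, no measurable
#' diversity), which also makes the bias 0 for monomorphic replicates.
#'
#' @param ne_grid increasing vector of Ne values, e.g. `c(1e3, 1e4, 1e5, 1e6)`.
#' @param n_samples,mu,seq_length fixed simulation parameters.
#' @param n_reps replicates per Ne (>= 100 recommended).
#' @param seed optional integer seed.
#' @return data.frame: Ne, theta (per site), gd_all, gd_unique, bias,
#'   se_all, se_unique, se_bias, min_bias, n_negative (replicates with
#'   negative bias), mean_n_haplotypes.
#' @export
duplicate_allele_experiment <- function(ne_grid, n_samples = 10, mu = 2e-4,
                                        seq_length = 600, n_reps = 300,
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(ne_grid, function(Ne) {
    p <- coalescent_params(n_samples, Ne, mu, seq_length)
    all_v <- numeric(n_reps); uni_v <- numeric(n_reps); nh <- integer(n_reps)
    for (r in seq_len(n_reps)) {
      m <- sim_coalescent_matrix(p)
      all_v[r] <- nucleotide_diversity(m)
      key <- apply(m, 1, paste, collapse = "")
      um <- m[!duplicated(key), , drop = FALSE]
      nh[r] <- nrow(um)
      uni_v[r] <- if (nrow(um) < 2) 0 else nucleotide_diversity(um)
    }
    bias <- uni_v - all_v
    data.frame(Ne = Ne, theta = 2 * Ne * mu,
               gd_all = mean(all_v), gd_unique = mean(uni_v),
               bias = mean(bias),
               se_all = stats::sd(all_v) / sqrt(n_reps),
               se_unique = stats::sd(uni_v) / sqrt(n_reps),
               se_bias = stats::sd(bias) / sqrt(n_reps),
               min_bias = min(bias),
               n_negative = sum(bias < 0),
               mean_n_haplotypes = mean(nh))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
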