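## Synthetic BOLD-like worlds: coalescent sequence sets per OTU, grid-cell
## environments from Gaussian random fields, and a planted linear
## environment -> diversity relationship, so that every downstream stage has
## a known truth to be checked against.

.WORLD_PREDICTORS <- c("MTWM", "MTCM", "PWM", "PDM",
                       "temp_seasonality", "precip_seasonality",
                       "habitat_heterogeneity", "human_modification",
                       "temp_trend", "temp_variation",
                       "precip_trend", "precip_variation")

#' Specification of a synthetic world
#'
#' Defines the study conditions a generated dataset emulates: grid geometry,
#' sampling intensity, the spatial structure of the environment, and the
#' planted linear effect of each predictor on the cell-level diversity
#' target (the square-root genetic diversity mean).
#'
#' Defaults describe a small, densely sampled barcode survey: 600 bp
#' alignments (a typical trimmed COI fragment), 40 OTUs per cell with 4
#' allele copies each, per-OTU scaled mutation rates (theta) drawn from a
#' gamma distribution around the cell mean so within-cell diversities vary,
#' and environment fields with an 800 km autocorrelation range. The baseline
#' sqrt-GDM of 0.12 (raw pi about 0.014) matches diversity levels typical of
#' insect COI assemblages.
#'
#' @param n_rows,n_cols grid extent in cells.
#' @param cell_size cell side in metres (default 193000).
#' @param otus_per_cell,samples_per_otu sampling intensity.
#' @param seq_length alignment length (bp).
#' @param mu per-site per-generation mutation rate used to convert planted
#'   theta into an effective population size.
#' @param true_slopes named numeric: effect of each predictor (unit-variance
#'   field scale) on sqrt-GDM; unnamed predictors have effect 0.
#' @param base_eta baseline sqrt-GDM.
#' @param gp_range,gp_sd range (m) and marginal sd of the environment fields.
#' @param field_sd,noise_sd sd of the residual spatial field and iid noise
#'   on the sqrt-GDM scale.
#' @param theta_shape gamma shape of the per-OTU theta distribution.
#' @param order_probs named probabilities of taxonomic orders.
#' @param order_theta_mult named multipliers of theta per order (default 1).
#' @param multicell_otus,multicell_span number of OTUs planted across
#'   several consecutive cells, and how many cells each spans.
#' @return a `world_spec` list.
#' @export
world_spec <- function(n_rows = 4, n_cols = 6, cell_size = 193000,
                       otus_per_cell = 40, samples_per_otu = 4,
                       seq_length = 600, mu = 1e-7,
                       true_slopes = c(MTWM = 0.02, precip_seasonality = -0.012),
                       base_eta = 0.12,
                       gp_range = 8e5, gp_sd = 1,
                       field_sd = 0.01, noise_sd = 0.008,
                       theta_shape = 3,
                       order_probs = c(Diptera = 0.34, Lepidoptera = 0.32,
                                       Hymenoptera = 0.17, Coleoptera = 0.17),
                       order_theta_mult = NULL,
                       multicell_otus = 0, multicell_span = 3) {
  stopifnot(n_rows >= 1, n_cols >= 1, otus_per_cell >= 1, samples_per_otu >= 1)
  bad <- setdiff(names(true_slopes), .WORLD_PREDICTORS)
  if (length(bad)) stop("unknown predictor(s) in true_slopes: ", paste(bad, collapse = ", "))
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_size = cell_size,
                 otus_per_cell = otus_per_cell, samples_per_otu = samples_per_otu,
                 seq_length = seq_length, mu = mu,
                 true_slopes = true_slopes, base_eta = base_eta,
                 gp_range = gp_range, gp_sd = gp_sd,
                 field_sd = field_sd, noise_sd = noise_sd,
                 theta_shape = theta_shape,
                 order_probs = order_probs,
                 order_theta_mult = order_theta_mult,
                 multicell_otus = multicell_otus,
                 multicell_span = multicell_span),
            class = "world_spec")
}

#' Generate a synthetic BOLD-like dataset
#'
#' Builds the full input set for the pipeline: a BOLD-schema record table
#' with coordinates drawn inside each cell, per-OTU aligned sequences
#' simulated under the coalescent at the planted theta, an environment table
#' of spatially autocorrelated predictors, and a truth record (planted
#' slopes, per-cell linear predictor, per-OTU theta) against which pipeline
#' output can be asserted. All randomness derives from one master seed.
#'
#' @param spec a [world_spec()].
#' @param seed master integer seed.
#' @param dir optional directory; when given, writes `records.tsv`,
#'   `environment.csv`, `truth.json` and per-OTU-per-cell FASTA under
#'   `fasta/`.
#' @return list: `records` (data.frame), `env` (data.frame keyed by cell),
#'   `alignments` (named list of character vectors, one per cell-OTU),
#'   `truth`, `grid`, `centroids`.
#' @export
generate_world <- function(spec, seed = 1, dir = NULL) {
  stopifnot(inherits(spec, "world_spec"))
  set.seed(derive_seed(seed, 1L))
  grid <- grid_spec(spec$cell_size)
  cells <- expand.grid(row = seq_len(spec$n_rows) - 1L,
                       col = seq_len(spec$n_cols) - 1L)
  cents <- cell_centroids(cells, grid)
  n_cells <- nrow(cents)
  coords <- cbind(cents$x, cents$y)

  ## spatially autocorrelated unit-variance environment fields
  z <- sapply(.WORLD_PREDICTORS, function(v)
    sim_gp_field(coords, spec$gp_range, spec$gp_sd))
  env <- as.data.frame(z)
  ## MTCM expressed in degrees C so the freeze dichotomy is meaningful
  env$MTCM <- 5 + 10 * z[, "MTCM"]
  env$cell <- cents$cell
  env$continent <- ifelse(cells$col < spec$n_cols / 2, "ContinentA", "ContinentB")
  env$freeze <- env$MTCM <= 0

  slopes <- stats::setNames(rep(0, length(.WORLD_PREDICTORS)), .WORLD_PREDICTORS)
  slopes[names(spec$true_slopes)] <- spec$true_slopes
  w_field <- if (spec$field_sd > 0) sim_gp_field(coords, spec$gp_range, spec$field_sd)
             else rep(0, n_cells)
  eta <- spec$base_eta + drop(z %*% slopes) + w_field +
    stats::rnorm(n_cells, 0, spec$noise_sd)
  cell_mean_theta <- pmax(eta, 0.02)^2

  orders <- names(spec$order_probs)
  mult <- stats::setNames(rep(1, length(orders)), orders)
  if (!is.null(spec$order_theta_mult))
    mult[names(spec$order_theta_mult)] <- spec$order_theta_mult

  w <- grid$cell_size
  rec_list <- list()
  aln <- list()
  theta_truth <- list()
  ## multi-cell OTUs occupy spans of consecutive cells (linear index order)
  mc_assign <- list()
  if (spec$multicell_otus > 0) {
    for (i in seq_len(spec$multicell_otus)) {
      start <- ((i - 1) * spec$multicell_span) %% n_cells + 1
      span_cells <- ((start - 1 + seq_len(spec$multicell_span) - 1) %% n_cells) + 1
      mc_assign[[paste0("BOLD:MC", sprintf("%03d", i))]] <- unique(span_cells)
    }
  }

  make_otu <- function(ci, otu_id, order_name, theta) {
    n <- if (length(spec$samples_per_otu) == 2)
      sample(spec$samples_per_otu[1]:spec$samples_per_otu[2], 1)
      else spec$samples_per_otu
    Ne <- max(theta / (2 * spec$mu), 1)
    p <- coalescent_params(n, Ne, spec$mu, spec$seq_length)
    seqs <- apply(matrix(c("A", "C", "G", "T")[sim_coalescent_matrix(p)],
                         n, spec$seq_length), 1, paste, collapse = "")
    x0 <- grid$origin[1] + cells$col[ci] * w
    y0 <- grid$origin[2] + cells$row[ci] * w
    px <- stats::runif(n, x0, x0 + w * (1 - 1e-9))
    py <- stats::runif(n, y0, y0 + w * (1 - 1e-9))
    ll <- behrmann_inverse(px, py)
    data.frame(processid = paste0(otu_id, "-", cents$cell[ci], "-", seq_len(n)),
               bin_uri = otu_id, order_name = order_name,
               species_name = paste0("sp_", otu_id),
               lat = ll[, "lat"], lon = ll[, "lon"],
               country = env$continent[ci], continent = env$continent[ci],
               nucleotides = seqs, stringsAsFactors = FALSE)
  }

  for (ci in seq_len(n_cells)) {
    n_local <- spec$otus_per_cell
    order_draw <- sample(orders, n_local, replace = TRUE, prob = spec$order_probs)
    for (k in seq_len(n_local)) {
      otu_id <- sprintf("BOLD:%s%03d", cents$cell[ci], k)
      theta <- stats::rgamma(1, shape = spec$theta_shape,
                             rate = spec$theta_shape /
                               (cell_mean_theta[ci] * mult[order_draw[k]]))
      rec <- make_otu(ci, otu_id, order_draw[k], theta)
      rec_list[[length(rec_list) + 1]] <- rec
      aln[[paste0(cents$cell[ci], "__", otu_id)]] <- rec$nucleotides
      theta_truth[[paste0(cents$cell[ci], "__", otu_id)]] <- theta
    }
  }
  for (otu_id in names(mc_assign)) {
    for (ci in mc_assign[[otu_id]]) {
      theta <- stats::rgamma(1, shape = spec$theta_shape,
                             rate = spec$theta_shape / cell_mean_theta[ci])
      rec <- make_otu(ci, otu_id, orders[1], theta)
      rec_list[[length(rec_list) + 1]] <- rec
      aln[[paste0(cents$cell[ci], "__", otu_id)]] <- rec$nucleotides
      theta_truth[[paste0(cents$cell[ci], "__", otu_id)]] <- theta
    }
  }

  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL
  truth <- list(slopes = as.list(slopes), base_eta = spec$base_eta,
                eta = stats::setNames(as.list(eta), cents$cell),
                cell_mean_theta = stats::setNames(as.list(cell_mean_theta), cents$cell),
                theta = theta_truth,
                multicell = lapply(mc_assign, function(ix) cents$cell[ix]),
                seed = seed)
  ## per-record planted cell, in construction order (rec_list and aln are
  ## appended in lockstep)
  truth$record_cell <- unlist(lapply(seq_along(rec_list), function(j) {
    rep(sub("__.*$", "", names(aln)[j]), nrow(rec_list[[j]]))
  }))

  world <- list(records = records, env = env, alignments = aln,
                truth = truth, grid = grid, centroids = cents,
                spec = spec)
  if (!is.null(dir)) write_world(world, dir)
  world
}

#' Write a synthetic world to disk
#' @param world result of [generate_world()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_records(world$records, file.path(dir, "records.tsv"))
  utils::write.csv(world$env, file.path(dir, "environment.csv"), row.names = FALSE)
  fa_dir <- file.path(dir, "fasta")
  dir.create(fa_dir, showWarnings = FALSE)
  for (key in names(world$alignments)) {
    seqs <- world$alignments[[key]]
    names(seqs) <- paste0(key, "_", seq_along(seqs))
    write_fasta_seqs(seqs, file.path(fa_dir, paste0(gsub("[:]", "_", key), ".fasta")))
  }
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Inject labelled pathological records
#'
#' Adds records violating each quality filter so that filter counts can be
#' asserted exactly: over-length sequences (> 800 bp after trimming),
#' under-length sequences, end-gap-padded sequences whose trimmed length
#' falls below the minimum, records with missing coordinates, a listed
#' invasive species present on two continents, and an OTU with fewer than
#' three copies in a cell (which passes the record filters but must be
#' excluded from diversity).
#'
#' @param world a generated world.
#' @param n_long,n_short,n_endgap,n_ungeo,n_invasive_cells,n_low_copy counts
#'   of each pathology (invasive: records per continent, one OTU across two
#'   continents).
#' @return the world with modified `records` and a `pathology` truth entry
#'   holding the expected filter-report counts and the invasive list.
#' @export
inject_pathologies <- function(world, n_long = 5, n_short = 4, n_endgap = 3,
                               n_ungeo = 4, n_invasive_cells = 2, n_low_copy = 1) {
  rec <- world$records
  cents <- world$centroids
  base <- rec[1, , drop = FALSE]
  mk <- function(n, otu, order_name, seqs, lat, lon, continent = "ContinentA") {
    data.frame(processid = paste0(otu, "-", seq_len(n)),
               bin_uri = otu, order_name = order_name,
               species_name = paste0("sp_", otu),
               lat = lat, lon = lon,
               country = continent, continent = continent,
               nucleotides = seqs, stringsAsFactors = FALSE)
  }
  rand_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  lat0 <- base$lat; lon0 <- base$lon
  extra <- list()
  if (n_long > 0)
    extra$long <- mk(n_long, "BOLD:PATHLONG", "Diptera",
                     vapply(seq_len(n_long), function(i) rand_seq(850), ""),
                     lat0, lon0)
  if (n_short > 0)
    extra$short <- mk(n_short, "BOLD:PATHSHORT", "Diptera",
                      vapply(seq_len(n_short), function(i) rand_seq(350), ""),
                      lat0, lon0)
  if (n_endgap > 0)
    extra$endgap <- mk(n_endgap, "BOLD:PATHGAP", "Diptera",
                       vapply(seq_len(n_endgap), function(i)
                         paste0("-----", rand_seq(300), "-----"), ""),
                       lat0, lon0)
  if (n_ungeo > 0)
    extra$ungeo <- mk(n_ungeo, "BOLD:PATHGEO", "Diptera",
                      vapply(seq_len(n_ungeo), function(i) rand_seq(600), ""),
                      NA_real_, NA_real_)
  invasive_list <- character(0)
  if (n_invasive_cells > 0) {
    invasive_list <- "Invasivus exemplum"
    inv <- do.call(rbind, lapply(c("ContinentA", "ContinentB"), function(ct) {
      d <- mk(3, "BOLD:PATHINV", "Coleoptera",
              vapply(1:3, function(i) rand_seq(600), ""), lat0, lon0, ct)
      d$processid <- paste0(d$processid, "-", ct)
      d
    }))
    inv$species_name <- "Invasivus exemplum"
    extra$invasive <- inv
  }
  if (n_low_copy > 0)
    extra$low_copy <- do.call(rbind, lapply(seq_len(n_low_copy), function(k)
      mk(2, sprintf("BOLD:PATHFEW%02d", k), "Diptera",
         vapply(1:2, function(i) rand_seq(600), ""), lat0, lon0)))
  add <- do.call(rbind, extra)
  rownames(add) <- NULL
  n_invasive_records <- if (n_invasive_cells > 0) 6L else 0L
  world$records <- rbind(rec, add)
  world$truth$pathology <- list(
    expected_report = list(
      n_input = nrow(rec) + nrow(add),
      duplicate_record = 0L,
      too_long = n_long,
      too_short = n_short + n_endgap,
      ungeoreferenced = n_ungeo,
      invasive = n_invasive_records,
      retained = nrow(rec) + 2L * n_low_copy),
    n_low_copy_otus = n_low_copy,
    low_copy_otu = if (n_low_copy > 0) sprintf("BOLD:PATHFEW%02d", seq_len(n_low_copy)) else NULL,
    invasive_list = invasive_list)
  world
}

#' Simulate cell-level data with a planted regression structure
#'
#' A lighter companion to [generate_world()] for exercising the spatial
#' regression directly: cell coordinates uniform over a square study region,
#' predictors as unit-variance Gaussian random fields, and the response
#' `y = X beta + w + eps` with a spatial field `w` and iid noise. No
#' sequences are simulated; the response is the cell-level target itself.
#'
#' @param n_cells number of cells (default 200).
#' @param slopes named or unnamed numeric vector of true slopes (default
#'   `c(0.5, -0.3, 0)`).
#' @param extent side of the square study region in metres (default 5e6).
#' @param env_range autocorrelation range of the predictor fields.
#' @param field_range,field_sd range and sd of the residual spatial field
#'   (`field_sd = 0` disables it).
#' @param noise_sd iid noise sd (default 0.1).
#' @param seed integer seed.
#' @return list: y, X (matrix), coords, field, slopes, noise_sd.
#' @export
simulate_cell_data <- function(n_cells = 200, slopes = c(0.5, -0.3, 0),
                               extent = 5e6, env_range = 8e5,
                               field_range = 1.2e6, field_sd = 0.2,
                               noise_sd = 0.1, seed = 1) {
  set.seed(seed)
  coords <- cbind(x = stats::runif(n_cells, 0, extent),
                  y = stats::runif(n_cells, 0, extent))
  p <- length(slopes)
  X <- sapply(seq_len(p), function(j) sim_gp_field(coords, env_range, 1))
  colnames(X) <- names(slopes) %||% paste0("x", seq_len(p))
  if (is.null(names(slopes))) names(slopes) <- colnames(X)
  field <- if (field_sd > 0) sim_gp_field(coords, field_range, field_sd)
           else rep(0, n_cells)
  y <- drop(X %*% slopes) + field + stats::rnorm(n_cells, 0, noise_sd)
  list(y = y, X = X, coords = coords, field = field, slopes = slopes,
       noise_sd = noise_sd)
}
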