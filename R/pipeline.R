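## End-to-end orchestration: filter -> grid -> diversity -> spatial stats ->
## environmental model -> prediction -> extrapolation mask, with every
## intermediate table retained and a seeded run manifest.

#' Pipeline configuration
#'
#' @param records BOLD-schema data.frame, or path to a records TSV.
#' @param env environment data.frame keyed by `cell` (with `continent` and
#'   predictor columns), or path to a CSV.
#' @param invasive_list character vector of invasive taxa, or path to a CSV
#'   with a `taxon` column.
#' @param out_dir optional output directory; when given every stage table is
#'   written as CSV plus a JSON manifest.
#' @param resolution grid cell size in metres, one of 96500, 193000, 385900.
#' @param min_otus minimum OTUs per retained cell, one of
#'   10, 25, 50, 100, 150, 200.
#' @param min_copies minimum allele copies per OTU per cell (default 3).
#' @param predictors character vector of predictor columns to model (default:
#'   all numeric env columns except MTCM, which is reserved for the freeze
#'   dichotomy); collinearity pruning at `cor_threshold` is applied first.
#' @param cor_threshold collinearity prune threshold (default 0.75).
#' @param select_vars run forward CV variable selection before fitting.
#' @param gde_literal evaluate GDE with the literal unnormalised entropy
#'   (default FALSE: Hill-number normalisation).
#' @param gde_logit fit the GDE model on the logit scale.
#' @param train_fraction continent-stratified training fraction.
#' @param chains,iter_warmup,iter_sampling MCMC configuration for the
#'   pipeline fits (defaults 2, 500, 500 -- enough for the desk-scale
#'   problems the pipeline targets; raise for production fits).
#' @param n_knots,gp_range spatial-field configuration (see
#'   [fit_spatial_glmm()]).
#' @param seed master seed; all stage seeds derive from it.
#' @param verbose emit stage logs.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(records, env, invasive_list = character(),
                            out_dir = NULL,
                            resolution = 193000, min_otus = 25, min_copies = 3,
                            predictors = NULL, cor_threshold = 0.75,
                            select_vars = FALSE,
                            gde_literal = FALSE, gde_logit = FALSE,
                            train_fraction = 0.75,
                            chains = 2, iter_warmup = 500, iter_sampling = 500,
                            n_knots = 25, gp_range = NULL,
                            seed = 1, verbose = FALSE) {
  if (!resolution %in% c(96500, 193000, 385900))
    stop("resolution must be one of 96500, 193000, 385900")
  if (!min_otus %in% c(10, 25, 50, 100, 150, 200))
    stop("min_otus must be one of 10, 25, 50, 100, 150, 200")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full macrogenetic pipeline
#'
#' Executes filter -> grid -> diversity -> spatial statistics -> model ->
#' predict -> mask. If no cells survive the diversity thresholds the run
#' stops gracefully after the diversity stage with `status =
#' "no_cells_retained"`; partial outputs are retained. The modelling stage
#' fits the sqrt-GDM and GDE responses independently, reports test-set
#' bias/precision (slope, intercept, R2, RMSE of observed vs predicted --
#' the threshold-selection criterion), and masks predictions in non-analog
#' environments.
#'
#' @param config a [pipeline_config()].
#' @return list of stage outputs (class `pipeline_result`): `filter_report`,
#'   `records`, `summaries`, `centroids`, `stats`, `models`, `predictions`,
#'   `bias`, `manifest`, `status`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  t0 <- Sys.time()

  records <- if (is.character(cfg$records)) read_records(cfg$records) else cfg$records
  env <- if (is.character(cfg$env)) utils::read.csv(cfg$env, stringsAsFactors = FALSE) else cfg$env
  invasive <- if (is.character(cfg$invasive_list) && length(cfg$invasive_list) == 1 &&
                  file.exists(cfg$invasive_list)) read_invasive_list(cfg$invasive_list)
              else cfg$invasive_list

  ## stage: filter
  fl <- apply_filters(records, invasive)
  log_stage("filter", sprintf("retained %d/%d", fl$report$retained, fl$report$n_input),
            verbose = cfg$verbose)

  ## stage: grid
  grid <- grid_spec(cfg$resolution)
  cellinfo <- assign_cell(fl$records$lat, fl$records$lon, grid)
  recs <- cbind(fl$records, cellinfo)
  log_stage("grid", sprintf("%d occupied cells", length(unique(recs$cell))),
            verbose = cfg$verbose)

  ## stage: diversity
  summaries <- summarize_cells(recs, min_otus = cfg$min_otus,
                               min_copies = cfg$min_copies,
                               gde_normalize = !cfg$gde_literal)
  result <- list(config = cfg, filter_report = fl$report, records = recs,
                 summaries = summaries, status = "ok")
  class(result) <- "pipeline_result"
  if (nrow(summaries) == 0) {
    result$status <- "no_cells_retained"
    log_stage("diversity", "no cells retained; stopping", verbose = cfg$verbose)
    if (!is.null(cfg$out_dir)) write_pipeline_outputs(result)
    return(result)
  }
  log_stage("diversity", sprintf("%d cells retained", nrow(summaries)),
            verbose = cfg$verbose)

  cellkeys <- do.call(rbind, strsplit(sub("^r", "", summaries$cell), "c"))
  cents <- cell_centroids(data.frame(row = as.integer(cellkeys[, 1]),
                                     col = as.integer(cellkeys[, 2])), grid)
  result$centroids <- cents
  coords <- cbind(cents$x, cents$y)

  ## continent of a cell: majority continent of its records
  cell_cont <- vapply(summaries$cell, function(cl) {
    names(which.max(table(recs$continent[recs$cell == cl])))
  }, character(1))

  ## stage: spatial statistics
  stats_out <- list()
  ok_gde <- !is.na(summaries$gde)
  if (nrow(summaries) >= 10) {
    stats_out$gdm_gde <- tryCatch(
      modified_ttest(summaries$gdm[ok_gde], summaries$gde[ok_gde],
                     coords[ok_gde, , drop = FALSE]),
      error = function(e) e$message)
    stats_out$latitude <- list(
      gdm = tryCatch(quadratic_latitude_test(summaries$gdm, cents)$table,
                     error = function(e) e$message),
      gde = tryCatch(quadratic_latitude_test(summaries$gde[ok_gde],
                                             cents[ok_gde, , drop = FALSE])$table,
                     error = function(e) e$message))
  }
  stats_out$sampling <- pearson_sampling_checks(summaries)
  stats_out$occupancy <- occupancy_table(recs)
  result$stats <- stats_out
  log_stage("stats", "correlation tests done", verbose = cfg$verbose)

  ## stage: environment join + model
  env_cells <- match(summaries$cell, env$cell)
  if (any(is.na(env_cells))) stop("environment table lacks cells: ",
                                  paste(summaries$cell[is.na(env_cells)][1:3], collapse = ", "))
  envm <- env[env_cells, , drop = FALSE]
  num_cols <- names(envm)[vapply(envm, is.numeric, TRUE)]
  predictors <- cfg$predictors %||% setdiff(num_cols, c("MTCM"))
  pruned <- prune_collinear(envm[, predictors, drop = FALSE],
                            threshold = cfg$cor_threshold, priority = predictors)
  predictors <- pruned$retained
  if ("MTCM" %in% names(envm)) summaries$freeze <- envm$MTCM <= 0

  split <- split_train_test(cell_cont, fraction = cfg$train_fraction,
                            seed = derive_seed(cfg$seed, 3L))
  tr <- split$train; te <- split$test
  st <- standardize_env(envm[, predictors, drop = FALSE], train_idx = tr)
  Xall <- as.matrix(st$table)

  fit_one <- function(response, transform) {
    yv <- summaries[[response]]
    okr <- is.finite(yv)
    tr_ok <- intersect(tr, which(okr)); te_ok <- intersect(te, which(okr))
    preds <- predictors
    if (cfg$select_vars) {
      sel <- select_variables(yv[tr_ok], Xall[tr_ok, , drop = FALSE],
                              seed = derive_seed(cfg$seed, 5L))
      if (length(sel$selected)) preds <- sel$selected
    }
    fit <- fit_spatial_glmm(yv[tr_ok], Xall[tr_ok, preds, drop = FALSE],
                            coords[tr_ok, , drop = FALSE],
                            n_knots = cfg$n_knots, gp_range = cfg$gp_range,
                            chains = cfg$chains, iter_warmup = cfg$iter_warmup,
                            iter_sampling = cfg$iter_sampling,
                            transform = transform,
                            seed = derive_seed(cfg$seed, 7L))
    pred_te <- if (length(te_ok) >= 2)
      predict(fit, as.data.frame(Xall[te_ok, preds, drop = FALSE]),
              coords[te_ok, , drop = FALSE])
      else NULL
    bias <- if (!is.null(pred_te)) {
      obs <- yv[te_ok]
      cal <- stats::lm(obs ~ pred_te$median)
      data.frame(response = response,
                 slope = unname(stats::coef(cal)[2]),
                 intercept = unname(stats::coef(cal)[1]),
                 r2 = summary(cal)$r.squared,
                 rmse = sqrt(mean((obs - pred_te$median)^2)),
                 n_test = length(te_ok))
    } else NULL
    ## residual spatial autocorrelation check
    res <- residuals(fit)
    moran <- if (length(res) >= 10)
      morans_i(res, coords[tr_ok, , drop = FALSE], n_perm = 1000,
               seed = derive_seed(cfg$seed, 11L))
      else NULL
    list(fit = fit, test_prediction = pred_te, bias = bias, moran = moran,
         predictors = preds, train = tr_ok, test = te_ok)
  }

  models <- list(gdm = fit_one("gdm", "identity"),
                 gde = fit_one("gde", if (cfg$gde_logit) "logit" else "identity"))
  result$models <- models
  result$bias <- do.call(rbind, Filter(Negate(is.null),
                                       lapply(models, `[[`, "bias")))
  log_stage("model", "GLMM fits done", verbose = cfg$verbose)

  ## stage: predict all cells + MESS mask (prediction set = all retained
  ## cells; training environment = training cells)
  preds_all <- lapply(names(models), function(nm) {
    m <- models[[nm]]
    pr <- predict(m$fit, as.data.frame(Xall[, m$predictors, drop = FALSE]), coords)
    pr <- cbind(data.frame(cell = summaries$cell), pr)
    mask_predictions(pr,
                     training_env = envm[tr, m$predictors, drop = FALSE],
                     prediction_env = envm[, m$predictors, drop = FALSE],
                     value_cols = c("median", "lower", "upper"))
  })
  names(preds_all) <- names(models)
  result$predictions <- preds_all
  log_stage("predict", "posterior prediction + MESS mask done", verbose = cfg$verbose)

  result$manifest <- list(
    seed = cfg$seed, resolution = cfg$resolution, min_otus = cfg$min_otus,
    min_copies = cfg$min_copies, predictors = predictors,
    n_records_input = fl$report$n_input, n_records_retained = fl$report$retained,
    n_cells = nrow(summaries), train_cells = length(tr), test_cells = length(te),
    r_version = as.character(getRversion()),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("macrogd pipeline run:", x$status, "\n")
  cat(sprintf("  records retained: %d/%d; cells: %d\n",
              x$filter_report$retained, x$filter_report$n_input,
              nrow(x$summaries)))
  if (!is.null(x$bias)) {
    cat("  test-set bias/precision:\n")
    print(x$bias, row.names = FALSE)
  }
  invisible(x)
}

## Write every stage table as CSV plus the JSON manifest. CSV writing is
## deterministic, so identical seeds give byte-identical outputs.
write_pipeline_outputs <- function(result) {
  dir <- result$config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$filter_report, file.path(dir, "filter_report.csv"),
                   row.names = FALSE)
  utils::write.csv(result$summaries, file.path(dir, "cell_summaries.csv"),
                   row.names = FALSE)
  od <- attr(result$summaries, "otu_diversity")
  if (!is.null(od))
    utils::write.csv(od, file.path(dir, "otu_diversity.csv"), row.names = FALSE)
  if (!is.null(result$centroids))
    utils::write.csv(result$centroids, file.path(dir, "cell_centroids.csv"),
                     row.names = FALSE)
  if (!is.null(result$stats$sampling))
    utils::write.csv(result$stats$sampling, file.path(dir, "sampling_checks.csv"),
                     row.names = FALSE)
  if (!is.null(result$bias))
    utils::write.csv(result$bias, file.path(dir, "test_bias.csv"), row.names = FALSE)
  for (nm in names(result$predictions))
    utils::write.csv(result$predictions[[nm]],
                     file.path(dir, paste0("predictions_", nm, ".csv")),
                     row.names = FALSE)
  if (!is.null(result$models)) {
    for (nm in names(result$models)) {
      s <- summary(result$models[[nm]]$fit)
      tab <- cbind(parameter = rownames(s$coefficients), s$coefficients)
      utils::write.csv(tab, file.path(dir, paste0("model_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(result$manifest))
    jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Sweep the minimum-OTU threshold
#'
#' Re-runs the diversity and modelling stages at each threshold and tabulates
#' cells retained and test-set bias/precision, the evidence base for choosing
#' a threshold (lowest bias: calibration slope near 1 and intercept near 0;
#' highest precision: high R2, low RMSE).
#'
#' @param config a [pipeline_config()].
#' @param thresholds vector of min-OTU thresholds (subset of the menu).
#' @return list: `table` (one row per threshold per response) and `runs`.
#' @export
threshold_sweep <- function(config, thresholds = c(10, 25, 50, 100, 150, 200)) {
  runs <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$min_otus <- th
    cfg$out_dir <- NULL
    run_pipeline(cfg)
  })
  names(runs) <- as.character(thresholds)
  rows <- lapply(seq_along(thresholds), function(i) {
    r <- runs[[i]]
    if (r$status != "ok" || is.null(r$bias))
      return(data.frame(threshold = thresholds[i], n_cells = nrow(r$summaries),
                        response = NA_character_, slope = NA_real_,
                        intercept = NA_real_, r2 = NA_real_, rmse = NA_real_,
                        n_test = NA_integer_))
    cbind(threshold = thresholds[i], n_cells = nrow(r$summaries), r$bias)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, runs = runs)
}
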