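#' @include io.R comparison.R coupling.R synthesis.R config.R
NULL

.PAIR_KEYS <- vapply(.IMPROVEMENT_PAIRS,
                     function(p) paste0(.labelKey(p[1L]), "_vs_",
                                        .labelKey(p[2L])),
                     character(1))

## One flat results row per dataset; all canonical columns present (NA when
## a predictor set or pairing does not exist for the dataset).
.resultsRow <- function(cr, coupling = NULL) {
  row <- list(dataset_id = cr@datasetId,
              process_type = cr@metadata$process_type %||% NA_character_,
              environment_type = cr@metadata$environment_type %||%
                NA_character_,
              microbial_data_type = cr@metadata$microbial_data_type %||%
                NA_character_)
  for (lab in .SET_ORDER) {
    key <- .labelKey(lab)
    st <- cr@perSet[[lab]]
    row[[paste0("adj_r2_", key)]] <- st$adj_r2 %||% NA_real_
    row[[paste0("best_aicc_", key)]] <- st$best_aicc %||% NA_real_
    row[[paste0("n_models_", key)]] <- st$n_models %||% NA_integer_
  }
  for (pk in .PAIR_KEYS) {
    fl <- cr@improvement[[pk]]
    row[[paste0("improved_", pk)]] <- fl$improved %||% NA
    row[[paste0("statistical_", pk)]] <- fl$statistical %||% NA
    row[[paste0("ecological_", pk)]] <- fl$ecological %||% NA
    row[[paste0("delta_adj_r2_", pk)]] <- fl$delta_adj_r2 %||% NA_real_
  }
  if (!is.null(coupling)) {
    row$env_to_community_adj_r2 <- coupling$summary$env_to_community_adj_r2
    row$env_to_biomass_adj_r2 <- coupling$summary$env_to_biomass_adj_r2
    row$biomass_to_community_adj_r2 <-
      coupling$summary$biomass_to_community_adj_r2
    row$env_to_community_selected <- paste(
      coupling$env_to_community$selected_constraints %||% character(0),
      collapse = ",")
  } else {
    row$env_to_community_adj_r2 <- NA_real_
    row$env_to_biomass_adj_r2 <- NA_real_
    row$biomass_to_community_adj_r2 <- NA_real_
    row$env_to_community_selected <- NA_character_
  }
  as.data.frame(row, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Flatten comparison (and coupling) results into a results table
#'
#' @param comparisons list of [ComparisonResult-class].
#' @param couplings optional parallel list of [couplingReport()] outputs.
#' @return Data frame, one row per dataset, with adjusted R-squared, best
#'   AICc and model counts per predictor set, improvement flags and deltas
#'   per pair, and coupling columns.
#' @export
resultsTable <- function(comparisons, couplings = NULL) {
  rows <- lapply(seq_along(comparisons), function(i)
    .resultsRow(comparisons[[i]],
                if (!is.null(couplings)) couplings[[i]] else NULL))
  do.call(rbind, rows)
}

.comparisonToList <- function(cr) {
  list(dataset_id = cr@datasetId, metadata = cr@metadata,
       per_set = cr@perSet, improvement = cr@improvement, notes = cr@notes)
}

.couplingToList <- function(cp) {
  strip <- function(r) if (is.null(r)) NULL else unclass(r)
  list(env_to_community = strip(cp$env_to_community),
       env_to_biomass = strip(cp$env_to_biomass),
       biomass_to_community = strip(cp$biomass_to_community),
       skipped = cp$skipped, summary = cp$summary)
}

#' Run the full analysis pipeline over a dataset collection
#'
#' For every dataset: validate ([validateDataset()]; fatal checks isolate the
#' dataset as a recorded failure without stopping the run), compare predictor
#' sets ([compareDataset()]) and quantify predictor-set coupling
#' ([couplingReport()], seeded per dataset from `config$coupling$seed`).
#' Writes per-dataset `comparison.json` and `coupling.json`, a
#' collection-level `results.tsv`, `synthesis.json` / `synthesis.tsv`
#' ([synthesizeCollection()]), a markdown `report.md` and a `log.txt` with
#' every warning and per-dataset timing. With identical inputs, config and
#' seeds the outputs are byte-identical across runs.
#'
#' @param input a `DatasetCollection` from [generateCollection()], or the
#'   path of a directory containing `manifest.tsv` and dataset
#'   subdirectories.
#' @param out_dir output directory.
#' @param config a [pipelineConfig()].
#' @return Invisibly: list with `results` (data frame), `synthesis`,
#'   `failures`, `status` (0 = clean, 2 = partial failures) and `paths`.
#' @export
runPipeline <- function(input, out_dir, config = pipelineConfig()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(input)) {
    manifest <- read.delim(file.path(input, "manifest.tsv"), sep = "\t",
                           stringsAsFactors = FALSE)
    getDataset <- function(i)
      readDataset(file.path(input, manifest$path[i]), manifest[i, ])
  } else if (inherits(input, "DatasetCollection")) {
    manifest <- input$manifest
    getDataset <- function(i) input$datasets[[manifest$dataset_id[i]]]
  } else {
    .mmiStop("invalidArgumentError",
             "`input` must be a DatasetCollection or a directory path")
  }
  n <- nrow(manifest)
  coupling_seeds <- spawnSeeds(config$coupling$seed, n)
  log <- character(0)
  failures <- list()
  rows <- list()
  for (i in seq_len(n)) {
    id <- manifest$dataset_id[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      ds <- getDataset(i)
      for (msg in attr(ds, "log") %||% character(0))
        log <- c(log, sprintf("[%s] %s", id, msg))
      v <- validateDataset(ds)
      for (ck in v$report$checks)
        if (ck$status != "ok")
          log <- c(log, sprintf("[%s] %s: %s %s", id, ck$status, ck$name,
                                ck$detail))
      if (v$report$fatal)
        stop(structure(class = c("fatalValidationError", "mmiError",
                                 "error", "condition"),
                       list(message = "fatal validation failure",
                            call = NULL)))
      cr <- compareDataset(v$dataset, config)
      for (msg in cr@notes) log <- c(log, sprintf("[%s] %s", id, msg))
      cp <- couplingReport(v$dataset,
                           alpha = config$coupling$alpha,
                           n_perm = config$coupling$n_permutations,
                           seed = coupling_seeds[i],
                           community_response =
                             config$coupling$community_response)
      ds_dir <- file.path(out_dir, id)
      dir.create(ds_dir, showWarnings = FALSE)
      jsonlite::write_json(.comparisonToList(cr),
                           file.path(ds_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      jsonlite::write_json(.couplingToList(cp),
                           file.path(ds_dir, "coupling.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           na = "null")
      .resultsRow(cr, cp)
    }, mmiError = function(e) e, error = function(e) e)
    dt <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
      log <- c(log, sprintf("[%s] FAILED: %s (%.2fs)", id,
                            conditionMessage(res), dt))
    } else {
      rows[[id]] <- res
      log <- c(log, sprintf("[%s] ok (%.2fs)", id, dt))
    }
  }
  if (!length(rows))
    .mmiStop("pipelineError", "every dataset failed; nothing to synthesize")
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
  write.table(out, file.path(out_dir, "results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  synthesis <- synthesizeCollection(
    results, manifest,
    min_n = config$synthesis$min_subset_n,
    mw_comparisons = config$synthesis$mw_comparisons)
  jsonlite::write_json(lapply(synthesis$summaries, unclass),
                       file.path(out_dir, "synthesis.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  syn_tab <- synthesis$table
  if (nrow(syn_tab)) {
    st <- syn_tab
    num <- vapply(st, is.numeric, logical(1))
    st[num] <- lapply(st[num], function(v) sprintf("%.17g", v))
    write.table(st, file.path(out_dir, "synthesis.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }
  writeLines(renderReport(synthesis), file.path(out_dir, "report.md"))
  writeLines(log, file.path(out_dir, "log.txt"))
  status <- if (length(failures)) 2L else 0L
  invisible(list(results = results, synthesis = synthesis,
                 failures = failures, status = status,
                 paths = list(results = file.path(out_dir, "results.tsv"),
                              synthesis = file.path(out_dir,
                                                    "synthesis.json"),
                              report = file.path(out_dir, "report.md"),
                              log = file.path(out_dir, "log.txt"))))
}
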