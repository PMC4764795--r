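#' @include AllClasses.R
NULL

## Fixed delimited-text dialect: UTF-8, tab-separated, header row, first
## column = sample id, '.' decimal separator. Numbers are written with 17
## significant digits so a write/read round trip is value-identical.
.writeBlock <- function(m, ids, path, id_col = "sample_id") {
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  df <- cbind(setNames(data.frame(ids, stringsAsFactors = FALSE), id_col), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
}

.readBlock <- function(path, sep = "\t") {
  raw <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  if (!ncol(raw))
    .mmiStop("parseError", "%s: no columns", basename(path))
  ids <- raw[[1L]]
  vals <- raw[, -1L, drop = FALSE]
  out <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = list(ids, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(v) & !is.na(vals[[j]]) & nzchar(vals[[j]]) &
                   toupper(vals[[j]]) != "NA")
    if (length(bad))
      .mmiStop("parseError", "%s: non-numeric value '%s' at row %d, column '%s'",
               basename(path), vals[[j]][bad[1L]], bad[1L],
               colnames(vals)[j])
    out[, j] <- v
  }
  out
}

#' Write one dataset as a directory of delimited text tables
#'
#' Layout: `env.tsv`, `community.tsv` (or `genes.tsv` for the
#' functional-gene flavor), optional `biomass.tsv`, `process.tsv` — each with
#' a `sample_id` first column and a header row — plus `truth.json` for
#' simulated datasets. [readDataset()] inverts this exactly.
#'
#' @param dataset a [ProcessDataset-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest row for the dataset.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- sampleIds(dataset)
  .writeBlock(envData(dataset), ids, file.path(dir, "env.tsv"))
  comm_file <- if (identical(datasetMetadata(dataset)$data_flavor,
                             "functional_gene")) "genes.tsv" else
    "community.tsv"
  .writeBlock(communityData(dataset), ids, file.path(dir, comm_file))
  if (!is.null(biomassData(dataset)))
    .writeBlock(matrix(biomassData(dataset), ncol = 1L,
                       dimnames = list(NULL, "biomass")),
                ids, file.path(dir, "biomass.tsv"))
  .writeBlock(matrix(processRate(dataset), ncol = 1L,
                     dimnames = list(NULL, "process")),
              ids, file.path(dir, "process.tsv"))
  truth <- truthRecord(dataset)
  if (length(truth))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         matrix = "rowmajor", na = "null")
  md <- datasetMetadata(dataset)
  invisible(data.frame(dataset_id = datasetId(dataset),
                       process_type = md$process_type %||% NA_character_,
                       environment_type = md$environment_type %||% NA_character_,
                       microbial_data_type =
                         md$microbial_data_type %||% NA_character_,
                       path = basename(dir),
                       stringsAsFactors = FALSE))
}

#' Write a whole collection plus its manifest
#'
#' @param collection a `DatasetCollection` from [generateCollection()].
#' @param dir output directory; one subdirectory per dataset plus
#'   `manifest.tsv`.
#' @return Invisibly, the manifest data frame.
#' @export
writeCollection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ds in collection$datasets)
    writeDataset(ds, file.path(dir, datasetId(ds)))
  write.table(collection$manifest, file.path(dir, "manifest.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(collection$manifest)
}

#' Read one dataset from a directory of delimited tables
#'
#' Requires `env.tsv`, `process.tsv` and at least one of `community.tsv` /
#' `genes.tsv`; `biomass.tsv` is optional. Blocks are aligned on the
#' intersection of their sample ids (in the order of `env.tsv`), samples
#' missing any required value are dropped listwise, and every dropped sample
#' is listed in the `"log"` attribute of the returned object. Fewer than 8
#' aligned samples is an error; non-numeric cells raise a parse error naming
#' the row and column.
#'
#' @param dir dataset directory.
#' @param manifest_row optional one-row data frame supplying the categorical
#'   metadata (process/environment/data type).
#' @param sep field separator (`"\t"` default; `","` accepted).
#' @return A [ProcessDataset-class] with a `"log"` attribute of ingestion
#'   messages.
#' @export
readDataset <- function(dir, manifest_row = NULL, sep = "\t") {
  need <- file.path(dir, c("env.tsv", "process.tsv"))
  for (f in need)
    if (!file.exists(f))
      .mmiStop("missingFileError", "required file %s not found", f)
  env <- .readBlock(file.path(dir, "env.tsv"), sep)
  proc <- .readBlock(file.path(dir, "process.tsv"), sep)
  comm_path <- file.path(dir, "community.tsv")
  genes_path <- file.path(dir, "genes.tsv")
  flavor <- NULL
  if (file.exists(comm_path)) {
    comm <- .readBlock(comm_path, sep)
  } else if (file.exists(genes_path)) {
    comm <- .readBlock(genes_path, sep)
    flavor <- "functional_gene"
  } else {
    .mmiStop("missingFileError",
             "neither community.tsv nor genes.tsv found in %s", dir)
  }
  bio_path <- file.path(dir, "biomass.tsv")
  bio <- if (file.exists(bio_path)) .readBlock(bio_path, sep) else NULL

  log <- character(0)
  ids <- rownames(env)
  for (block in c(list(proc, comm), if (!is.null(bio)) list(bio))) {
    lost <- setdiff(ids, rownames(block))
    if (length(lost))
      log <- c(log, sprintf("sample %s dropped: absent from some block", lost))
    ids <- intersect(ids, rownames(block))
  }
  env <- env[ids, , drop = FALSE]
  comm <- comm[ids, , drop = FALSE]
  proc <- proc[ids, , drop = FALSE]
  if (!is.null(bio)) bio <- bio[ids, , drop = FALSE]
  complete <- !(rowSums(is.na(env)) | rowSums(is.na(comm)) |
                  rowSums(is.na(proc)) |
                  (if (is.null(bio)) 0 else rowSums(is.na(bio))))
  if (any(!complete))
    log <- c(log, sprintf("sample %s dropped: missing value (listwise deletion)",
                          ids[!complete]))
  ids <- ids[complete]
  if (length(ids) < 8L)
    .mmiStop("datasetTooSmallError",
             "only %d aligned complete samples (need >= 8)", length(ids))
  env <- env[ids, , drop = FALSE]
  comm <- comm[ids, , drop = FALSE]
  process <- setNames(proc[ids, 1L], ids)
  biomass <- if (is.null(bio)) numeric(0) else setNames(bio[ids, 1L], ids)

  md <- list(
    process_type = manifest_row$process_type %||% NA_character_,
    environment_type = manifest_row$environment_type %||% NA_character_,
    microbial_data_type = manifest_row$microbial_data_type %||% NA_character_
  )
  md$data_flavor <- flavor %||%
    (if (identical(md$microbial_data_type, "PLFA")) "plfa"
     else "abundance_table")
  truth_path <- file.path(dir, "truth.json")
  truth <- if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    if (!is.null(tr$latent_axes)) tr$latent_axes <- as.matrix(tr$latent_axes)
    tr
  } else list()
  ds <- new("ProcessDataset",
            datasetId = as.character(manifest_row$dataset_id %||%
                                       basename(dir)),
            env = env, community = comm, biomass = biomass,
            process = process, metadata = md, truth = truth)
  attr(ds, "log") <- log
  ds
}

#' Validate (and clean) a dataset before analysis
#'
#' Checks run, in order: constant environmental columns (dropped, warning);
#' near-perfect collinearity between environmental columns (absolute
#' correlation above 0.99 — the later column is dropped, warning); negative
#' community abundances (fatal); zero-variance response (fatal); constant
#' biomass (dropped, warning). Nothing stops here — the report carries the
#' status, and `fatal = TRUE` tells the pipeline to skip the dataset.
#'
#' @param dataset a [ProcessDataset-class].
#' @return List with `dataset` (cleaned) and `report` (a
#'   `ValidationReport`: checks, statuses, `fatal` flag).
#' @export
validateDataset <- function(dataset) {
  checks <- list()
  addCheck <- function(name, status, detail = "")
    checks[[length(checks) + 1L]] <<- list(name = name, status = status,
                                           detail = detail)
  env <- envData(dataset)
  sds <- apply(env, 2L, sd)
  const <- colnames(env)[sds == 0]
  if (length(const)) {
    env <- env[, setdiff(colnames(env), const), drop = FALSE]
    addCheck("constant_env_columns", "warning",
             paste("dropped:", paste(const, collapse = ", ")))
  } else addCheck("constant_env_columns", "ok")
  if (ncol(env) >= 2L) {
    cm <- abs(cor(env))
    drop <- character(0)
    for (j in 2:ncol(env))
      if (any(cm[seq_len(j - 1L), j] > 0.99)) drop <- c(drop, colnames(env)[j])
    if (length(drop)) {
      env <- env[, setdiff(colnames(env), drop), drop = FALSE]
      addCheck("collinear_env_columns", "warning",
               paste("dropped:", paste(drop, collapse = ", ")))
    } else addCheck("collinear_env_columns", "ok")
  } else addCheck("collinear_env_columns", "ok")
  fatal <- FALSE
  if (length(communityData(dataset)) && min(communityData(dataset)) < 0) {
    addCheck("negative_community_entries", "fatal",
             "community abundances must be nonnegative")
    fatal <- TRUE
  } else addCheck("negative_community_entries", "ok")
  if (var(processRate(dataset)) == 0) {
    addCheck("zero_variance_response", "fatal",
             "process rate is constant")
    fatal <- TRUE
  } else addCheck("zero_variance_response", "ok")
  biomass <- dataset@biomass
  if (length(biomass) && sd(biomass) == 0) {
    biomass <- numeric(0)
    addCheck("constant_biomass", "warning", "biomass dropped (constant)")
  }
  cleaned <- dataset
  if (!fatal) {
    if (!ncol(env))
      .mmiStop("missingBaselineError",
               "no environmental variables remain after validation")
    cleaned@env <- env
    cleaned@biomass <- biomass
    methods::validObject(cleaned)
  }
  report <- structure(list(dataset_id = datasetId(dataset),
                           checks = checks, fatal = fatal),
                      class = "ValidationReport")
  list(dataset = cleaned, report = report)
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport for \"", x$dataset_id, "\" (fatal = ", x$fatal,
      ")\n", sep = "")
  for (ck in x$checks)
    cat(sprintf("  [%s] %s %s\n", ck$status, ck$name,
                if (nzchar(ck$detail)) paste0("- ", ck$detail) else ""))
  invisible(x)
}
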