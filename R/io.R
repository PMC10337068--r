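#' Read a delimited expression matrix
#'
#' Reads a CSV/TSV matrix with an id header row and an id first column.
#' Expression exports often store features (probes/genes) as rows and samples
#' as columns; pass `orientation = "features-by-samples"` to transpose on
#' load so the result is always samples x features.
#'
#' @param path delimited text file; the delimiter is inferred from the
#'   extension (`.csv` vs anything else = tab) unless given.
#' @param orientation `"samples-by-features"` (default) or
#'   `"features-by-samples"`.
#' @param delimiter optional field separator override.
#' @param missing how to handle missing values: `"error"` (default),
#'   `"drop-feature"` (remove features with any NA, with a warning) or
#'   `"impute-mean"` (replace by the feature mean).
#' @return Numeric samples-by-features matrix with unique feature names.
#' @export
read_matrix <- function(path,
                        orientation = c("samples-by-features",
                                        "features-by-samples"),
                        delimiter = NULL,
                        missing = c("error", "drop-feature", "impute-mean")) {
  orientation <- match.arg(orientation)
  missing <- match.arg(missing)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  header <- strsplit(readLines(path, n = 1), delimiter, fixed = TRUE)[[1]][-1]
  if (anyDuplicated(header))
    stop("duplicate feature ids in ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE)
  ids <- as.character(dt[[1]])
  body <- dt[, -1, drop = FALSE]
  non_num <- !vapply(body, is.numeric, logical(1))
  if (any(non_num))
    stop(sprintf("non-numeric values in column(s): %s",
                 paste(utils::head(names(body)[non_num], 5), collapse = ", ")),
         call. = FALSE)
  X <- as.matrix(body)
  rownames(X) <- ids
  if (orientation == "features-by-samples") X <- t(X)
  if (anyDuplicated(colnames(X)))
    stop("duplicate feature ids in ", path, call. = FALSE)
  if (anyNA(X)) {
    if (missing == "error")
      stop("missing values in ", path,
           " (use missing = 'drop-feature' or 'impute-mean')", call. = FALSE)
    bad <- which(apply(X, 2, anyNA))
    if (missing == "drop-feature") {
      warning(sprintf("dropping %d feature(s) with missing values", length(bad)),
              call. = FALSE)
      X <- X[, -bad, drop = FALSE]
    } else {
      for (j in bad) X[is.na(X[, j]), j] <- mean(X[, j], na.rm = TRUE)
      warning(sprintf("mean-imputed missing values in %d feature(s)", length(bad)),
              call. = FALSE)
    }
  }
  if (nrow(X) < 2) stop("need at least 2 samples", call. = FALSE)
  X
}

#' Write a matrix as TSV (samples x features, id column first)
#'
#' @param X numeric matrix with dimnames.
#' @param path output file.
#' @export
write_matrix <- function(X, path) {
  df <- data.frame(sample = rownames(X), X, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a two-column labels file (sample id, group label)
#'
#' @param path TSV/CSV file; first column sample ids, second labels.
#' @return Named vector of labels.
#' @export
read_labels <- function(path) {
  delim <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- data.table::fread(path, sep = delim, header = TRUE, data.table = FALSE)
  stats::setNames(df[[2]], as.character(df[[1]]))
}

MODEL_FORMAT_VERSION <- 1L

#' Persist / restore a fitted kernel PCA model
#'
#' The archive stores the preprocessed training matrix, the Gram matrix and
#' its centering statistics, the dual coefficients and the kernel spec, so
#' every downstream operation (projection, ranking, plots) reproduces its
#' pre-save output exactly.
#'
#' @param model a `kpca_model`.
#' @param path archive path (an RDS file).
#' @export
save_model <- function(model, path) {
  if (!inherits(model, "kpca_model")) stop("'model' must be a kpca_model",
                                           call. = FALSE)
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model archive ", path, ": ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || is.null(obj$format_version) ||
      !inherits(obj$model, "kpca_model"))
    stop("not a kpcaig model archive: ", path, call. = FALSE)
  if (obj$format_version != MODEL_FORMAT_VERSION)
    stop(sprintf("model archive version %s not supported (expected %s)",
                 obj$format_version, MODEL_FORMAT_VERSION), call. = FALSE)
  obj$model
}

#' Run the fit -> rank pipeline and write its artifacts
#'
#' Fits kernel PCA on a matrix (selecting the RBF bandwidth on a grid when
#' none is fixed), ranks all features, and writes the ranking plus a JSON run
#' manifest recording every parameter, the selected bandwidth and its search
#' table, file checksums and timings — enough to reproduce the outputs.
#'
#' @param input path to the expression matrix, or a numeric matrix.
#' @param output_dir directory for the artifacts (created if needed).
#' @param kernel `"rbf"` or `"linear"`.
#' @param sigma fixed RBF bandwidth, or `NULL` to select on `sigma_grid`.
#' @param sigma_grid candidate bandwidths used when `sigma` is `NULL`.
#' @param q retained components.
#' @param scale z-score features before the kernel.
#' @param score_scale multiplier applied to scores in the written table.
#' @param orientation,missing passed to [read_matrix()] when `input` is a path.
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return List with `model`, `ranking` and the `manifest` (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(input, output_dir, kernel = "rbf", sigma = NULL,
                         sigma_grid = default_sigma_grid(), q = 2,
                         scale = TRUE, score_scale = 1,
                         orientation = "samples-by-features",
                         missing = "error", seed = 1) {
  t0 <- proc.time()[["elapsed"]]
  X <- if (is.character(input))
    read_matrix(input, orientation = orientation, missing = missing)
  else as_data_matrix(input)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  sigma_table <- NULL
  spec <- if (kernel == "linear") {
    linear_kernel()
  } else {
    if (is.null(sigma)) {
      sigma <- select_sigma(X, grid = sigma_grid, q = q, scale = scale)
      sigma_table <- attr(sigma, "table")
    }
    rbf_kernel(as.numeric(sigma))
  }
  model <- kpca_fit(X, spec, q = q, scale = scale)
  ranking <- rank_features(model)
  ranking_path <- file.path(output_dir, "ranking.tsv")
  write_ranking(ranking, ranking_path, scale = score_scale)
  model_path <- file.path(output_dir, "model.rds")
  save_model(model, model_path)
  manifest <- list(
    package = "kpcaig",
    version = as.character(utils::packageVersion("kpcaig")),
    input = if (is.character(input)) input else "<in-memory matrix>",
    n = nrow(X), p = ncol(X),
    kernel = spec$family,
    sigma = if (spec$family == "rbf") spec$sigma else NULL,
    sigma_table = sigma_table,
    q = model$q, scale = scale, score_scale = score_scale, seed = seed,
    explained_variance = explained_variance(model),
    outputs = list(
      ranking = list(path = "ranking.tsv",
                     md5 = unname(tools::md5sum(ranking_path))),
      model = list(path = "model.rds",
                   md5 = unname(tools::md5sum(model_path)))),
    elapsed_seconds = proc.time()[["elapsed"]] - t0)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(model = model, ranking = ranking, manifest = manifest))
}
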