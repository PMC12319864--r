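#' Write a connectivity matrix
#'
#' MatrixMarket coordinate format (`.mtx`, via the Matrix package) or dense
#' CSV (any other extension; header row of vertex ids, first column of seed
#' ids). A JSON sidecar (`<path>.json`) records the processing state and
#' the id lists so the round trip is lossless.
#'
#' @param matrix a [connectivity_matrix()].
#' @param path output path; `.mtx` selects MatrixMarket.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "connectivity_matrix"))
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(matrix$values, sparse = TRUE), path)
  } else {
    df <- data.frame(seed_id = matrix$seed_ids, matrix$values,
                     check.names = FALSE)
    names(df) <- c("seed_id", matrix$vertex_ids)
    utils::write.csv(df, path, row.names = FALSE)
  }
  jsonlite::write_json(
    list(state = matrix$state, seed_ids = matrix$seed_ids,
         vertex_ids = matrix$vertex_ids),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a connectivity matrix written by [write_matrix()]
#'
#' @param path `.mtx` or CSV path; the `<path>.json` sidecar, if present,
#'   restores state and ids.
#' @return A [connectivity_matrix()].
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty file: ", path)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar,
                                                        simplifyVector = TRUE)
          else NULL
  if (grepl("\\.mtx$", path)) {
    vals <- as.matrix(Matrix::readMM(path))
    seed_ids <- if (!is.null(meta)) meta$seed_ids else seq_len(nrow(vals)) - 1L
    vertex_ids <- if (!is.null(meta)) meta$vertex_ids
                  else seq_len(ncol(vals)) - 1L
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    if (names(df)[1] != "seed_id")
      stop(path, ": first CSV column must be 'seed_id', found '",
           names(df)[1], "' (line 1)")
    if (anyDuplicated(df$seed_id)) {
      dup <- df$seed_id[duplicated(df$seed_id)][1]
      stop(path, ": duplicate seed id ", dup, " (line ",
           which(df$seed_id == dup)[2] + 1, ")")
    }
    seed_ids <- df$seed_id
    vertex_ids <- as.integer(names(df)[-1])
    vals <- as.matrix(df[, -1, drop = FALSE])
    dimnames(vals) <- NULL
  }
  state <- if (!is.null(meta)) meta$state else "raw"
  if (!is.null(meta)) {
    if (!identical(as.integer(meta$seed_ids), as.integer(seed_ids)))
      stop(path, ": seed ids disagree with sidecar")
    if (length(meta$vertex_ids) != ncol(vals))
      stop(path, ": sidecar vertex count (", length(meta$vertex_ids),
           ") does not match matrix columns (", ncol(vals), ")")
  }
  connectivity_matrix(vals, seed_ids = seed_ids, vertex_ids = vertex_ids,
                      state = state)
}

#' Write / read streamline endpoint tables
#'
#' Tab-separated with header `seed_id, x, y, z, fa`.
#'
#' @param endpoints endpoint data.frame.
#' @param path file path.
#' @return `path` (write) or the endpoint data.frame (read).
#' @export
write_endpoints <- function(endpoints, path) {
  req <- c("seed_id", "x", "y", "z", "fa")
  if (!all(req %in% names(endpoints)))
    stop("endpoint table must have columns ", paste(req, collapse = ", "))
  utils::write.table(endpoints[, req], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_endpoints
#' @export
read_endpoints <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path)
  req <- c("seed_id", "x", "y", "z", "fa")
  if (!all(req %in% names(df)))
    stop(path, ": expected columns ", paste(req, collapse = ", "))
  if (any(df$fa < 0)) stop(path, ": negative FA weight")
  df
}

#' Write / read phenotype tables
#'
#' Tab-separated with header `subject_id, scan_age_weeks, birth_age_weeks,
#' sex, group, in_template`.
#'
#' @param phenotypes phenotype data.frame.
#' @param path file path.
#' @return `path` (write) or the phenotype data.frame (read).
#' @export
write_phenotypes <- function(phenotypes, path) {
  req <- c("subject_id", "scan_age_weeks", "birth_age_weeks", "sex",
           "group", "in_template")
  if (!all(req %in% names(phenotypes)))
    stop("phenotype table must have columns ", paste(req, collapse = ", "))
  utils::write.table(phenotypes[, req], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "scan_age_weeks", "birth_age_weeks", "sex",
           "group", "in_template")
  if (!all(req %in% names(df)))
    stop(path, ": expected columns ", paste(req, collapse = ", "))
  df$in_template <- as.logical(df$in_template)
  df
}

#' Serialize a decomposition
#'
#' Scores as TSV (`seed_id` + one column per component), loadings as TSV
#' (`vertex_id` + components), and metadata (singular values, variance
#' fractions, k) as JSON.
#'
#' @param decomposition a [pca_svd()] result.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return The directory, invisibly.
#' @export
write_decomposition <- function(decomposition, dir, prefix = "decomposition") {
  stopifnot(inherits(decomposition, "decomposition"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- decomposition$k
  comp_names <- paste0("PC", seq_len(k))
  scores <- data.frame(seed_id = decomposition$seed_ids,
                       decomposition$scores)
  names(scores) <- c("seed_id", comp_names)
  utils::write.table(scores, file.path(dir, paste0(prefix, "_scores.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  loadings <- data.frame(vertex_id = decomposition$vertex_ids,
                         decomposition$loadings)
  names(loadings) <- c("vertex_id", comp_names)
  utils::write.table(loadings, file.path(dir, paste0(prefix, "_loadings.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(k = k, singular_values = decomposition$singular_values,
         variance_explained = decomposition$variance_explained,
         variance_fraction = decomposition$variance_fraction,
         total_variance = decomposition$total_variance,
         n_seeds = decomposition$n_seeds),
    file.path(dir, paste0(prefix, "_meta.json")), auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

#' Write a stat map as TSV
#'
#' Columns `id, statistic, p, p_adjusted, mask`.
#'
#' @param map a [stat_map()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  df <- data.frame(id = map$ids, statistic = map$statistic, p = map$p,
                   p_adjusted = if (is.null(map$p_adjusted)) NA
                                else map$p_adjusted,
                   mask = if (is.null(map$mask)) NA else map$mask)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
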