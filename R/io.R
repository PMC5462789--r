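# Delimited-matrix + JSON-sidecar readers and writers.

write_tsv_matrix <- function(m, path, col_names = TRUE) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col_names)
  invisible(path)
}

#' Write a region time series as TSV with a JSON sidecar
#'
#' The matrix goes to `<path>.tsv` (rows = regions) and sampling metadata
#' (fs, band, labels, and any extra provenance fields such as the
#' generator config echo) to `<path>.json`.
#'
#' @param ts a [region_ts()] or `scalp_rec`.
#' @param path output path stem (no extension).
#' @param extra named list merged into the sidecar.
#' @return the path stem, invisibly.
#' @export
write_region_ts <- function(ts, path, extra = list()) {
  write_tsv_matrix(ts$data, paste0(path, ".tsv"), col_names = FALSE)
  meta <- c(list(fs = ts$fs,
                 band = if (is.numeric(ts$band)) ts$band else "broadband",
                 labels = ts$region_labels %||% ts$channel_labels,
                 n_samples = ncol(ts$data)),
            extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a region time series written by [write_region_ts()]
#'
#' @param path path stem (no extension).
#' @return a [region_ts()].
#' @export
read_region_ts <- function(path) {
  m <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  band <- if (is.character(meta$band)) meta$band else as.numeric(meta$band)
  region_ts(unname(m), meta$fs, band, meta$labels)
}

#' Write a connectivity or transition matrix as labelled TSV
#'
#' @param m matrix with node labels as dimnames (or none).
#' @param path output file.
#' @export
write_conn_matrix <- function(m, path) {
  df <- as.data.frame(unclass(m))
  names(df) <- colnames(m) %||% paste0("R", seq_len(ncol(m)))
  write_tsv_matrix(df, path)
}

#' Write a partition as two-column TSV (node, module)
#'
#' @param part membership vector.
#' @param path output file.
#' @export
write_partition <- function(part, path) {
  write_tsv_matrix(
    data.frame(node = names(part) %||% seq_along(part),
               module = as.integer(part)), path)
}

#' Write ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output file.
#' @export
write_ground_truth <- function(truth, path) {
  cfg <- truth$config
  cfg$membership <- NULL
  jsonlite::write_json(
    list(partition = as.integer(truth$partition),
         regimes = lapply(truth$regimes, function(r)
           list(start = r$start, end = r$end, roles = unname(r$roles))),
         config = cfg[!vapply(cfg, is.null, TRUE)]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}
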