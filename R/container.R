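# Native columnar phase-space container: a flat binary block of doubles
# (column after column, little-endian) plus a JSON metadata sidecar. This is
# the package's lossless interchange format; the IAEA dialect (single
# precision) is import/export.

#' Write a phase-space store in the native columnar container
#'
#' @param store a [phsp_store()].
#' @param path base path; `<path>.fphsp` (binary columns) and
#'   `<path>.json` (metadata) are written.
#' @return invisibly, the binary path.
#' @export
write_phsp <- function(store, path) {
  bin_path <- paste0(path, ".fphsp")
  meta_path <- paste0(path, ".json")
  cols <- PHSP_COLUMNS
  meta <- list(
    format = "fajtrace-phsp-v1",
    columns = cols,
    n = nrow(store),
    z_plane = attr(store, "z_plane"),
    n_original_histories = attr(store, "n_original_histories"),
    counts_by_kind = as.list(counts_by_kind(store))
  )
  extra <- setdiff(names(store), cols)
  if (length(extra)) meta$extra_columns <- extra
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  con <- file(bin_path, "wb")
  on.exit(close(con))
  for (col in c(cols, extra)) {
    writeBin(as.numeric(store[[col]]), con, size = 8L, endian = "little")
  }
  invisible(bin_path)
}

#' Read a phase-space store from the native columnar container
#'
#' @param path base path as given to [write_phsp()].
#' @return a [phsp_store()].
#' @export
read_phsp <- function(path) {
  bin_path <- paste0(path, ".fphsp")
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("metadata sidecar not found: ", meta_path)
  if (!file.exists(bin_path)) stop("binary file not found: ", bin_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "fajtrace-phsp-v1")) {
    stop("unrecognized container format: ", meta$format)
  }
  n <- as.integer(meta$n)
  cols <- c(meta$columns, meta$extra_columns)
  con <- file(bin_path, "rb")
  on.exit(close(con))
  values <- lapply(cols, function(col) {
    readBin(con, "numeric", n = n, size = 8L, endian = "little")
  })
  names(values) <- cols
  df <- as.data.frame(values)
  df$kind <- as.integer(df$kind)
  df$new_history <- as.logical(df$new_history)
  phsp_store(df, z_plane = meta$z_plane,
             n_original_histories = meta$n_original_histories,
             validate = FALSE)
}
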