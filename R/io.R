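#' Array container with a JSON metadata sidecar
#'
#' Numeric arrays (epochs, fit maps, factor sets) are persisted with R
#' native serialization plus a `<path>.json` sidecar recording dimensions,
#' dimension labels and arbitrary metadata, so consumers can check shapes
#' without loading the payload.
#'
#' @param x numeric array or matrix.
#' @param path file path.
#' @param dimLabels optional character vector naming the dimensions.
#' @param meta named list of extra metadata.
#' @return `writeArray()` the path invisibly; `readArray()` a list with
#'   `data` and `meta`.
#' @export
writeArray <- function(x, path, dimLabels = NULL, meta = list()) {
  saveRDS(x, path)
  jsonlite::write_json(
    c(list(dim = dim(x) %||% length(x), dim_labels = dimLabels), meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeArray
#' @export
readArray <- function(path) {
  list(data = readRDS(path),
       meta = jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE))
}

#' Serialize a probe model
#'
#' The transform matrix as tab-separated text with the training metadata in
#' a JSON sidecar.
#'
#' @param probe a [ProbeModel-class].
#' @param path file path for the transform matrix.
#' @return `writeProbe()` the path invisibly; `readProbe()` a
#'   [ProbeModel-class] (restart transforms are not round-tripped).
#' @export
writeProbe <- function(probe, path) {
  stopifnot(is(probe, "ProbeModel"))
  utils::write.table(probe@transform, path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- probe@meta
  meta$restart_transforms <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeProbe
#' @export
readProbe <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("ProbeModel", transform = unname(m), meta = as.list(meta))
}
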