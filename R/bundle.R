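# Array-bundle container: a JSON sidecar describing named numeric arrays
# (dims, byte offsets) plus one raw little-endian float64 .bin file. Used as
# the on-disk fixture format for recordings, epoch sets and attention maps.

#' Write a bundle of named numeric arrays to disk
#'
#' Stores a named list of numeric vectors/matrices/arrays as a pair of files:
#' `<prefix>.json` (dimensions, order, metadata) and `<prefix>.bin` (raw
#' little-endian doubles, concatenated in listed order). Writes are exact:
#' doubles round-trip bit-for-bit.
#'
#' @param arrays named list of numeric arrays.
#' @param prefix path prefix (without extension).
#' @param meta optional list of scalar/vector metadata stored in the sidecar.
#' @return `prefix`, invisibly.
#' @seealso [read_array_bundle()]
#' @export
write_array_bundle <- function(arrays, prefix, meta = list()) {
  stopifnot(is.list(arrays), length(arrays) > 0, !is.null(names(arrays)))
  entries <- lapply(names(arrays), function(nm) {
    a <- arrays[[nm]]
    if (!is.numeric(a)) stop("array '", nm, "' is not numeric", call. = FALSE)
    list(name = nm, dim = if (is.null(dim(a))) length(a) else dim(a))
  })
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  for (nm in names(arrays))
    writeBin(as.double(arrays[[nm]]), con, size = 8L, endian = "little")
  jsonlite::write_json(
    list(format = "eegadapt-array-bundle", version = 1L,
         arrays = entries, meta = meta),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(prefix)
}

#' Read a bundle of named numeric arrays from disk
#'
#' @param prefix path prefix used in [write_array_bundle()].
#' @return list with elements `arrays` (named list of arrays) and `meta`.
#' @export
read_array_bundle <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  if (!identical(side$format, "eegadapt-array-bundle"))
    stop("not an eegadapt array bundle: ", prefix, call. = FALSE)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  arrays <- list()
  for (k in seq_len(nrow(side$arrays))) {
    dm <- unlist(side$arrays$dim[k])
    v <- readBin(con, "double", n = prod(dm), size = 8L, endian = "little")
    if (length(dm) > 1L) dim(v) <- dm
    arrays[[side$arrays$name[k]]] <- v
  }
  list(arrays = arrays, meta = side$meta)
}

#' Save / load a recording in the array-bundle format
#'
#' @param rec an [eeg_recording()].
#' @param prefix path prefix (no extension).
#' @return `prefix` invisibly (write); an `eeg_recording` (read).
#' @export
write_recording <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  write_array_bundle(list(samples = rec$samples), prefix,
                     meta = list(kind = "recording", fs = rec$fs,
                                 channel_labels = rec$channel_labels))
}

#' @rdname write_recording
#' @export
read_recording <- function(prefix) {
  b <- read_array_bundle(prefix)
  if (!identical(b$meta$kind, "recording"))
    stop("bundle at ", prefix, " does not hold a recording", call. = FALSE)
  eeg_recording(b$arrays$samples, b$meta$fs, b$meta$channel_labels)
}

#' Save / load an epoch set in the array-bundle format
#'
#' @param ep an [eeg_epochs()] object.
#' @param prefix path prefix (no extension).
#' @return `prefix` invisibly (write); an `eeg_epochs` (read).
#' @export
write_epochs <- function(ep, prefix) {
  stopifnot(inherits(ep, "eeg_epochs"))
  write_array_bundle(
    list(epochs = ep$epochs, start_times = ep$start_times), prefix,
    meta = list(kind = "epochs", fs = ep$fs, window_s = ep$window_s,
                labels = if (is.null(ep$labels)) NULL else as.character(ep$labels),
                channel_labels = ep$channel_labels))
}

#' @rdname write_epochs
#' @export
read_epochs <- function(prefix) {
  b <- read_array_bundle(prefix)
  if (!identical(b$meta$kind, "epochs"))
    stop("bundle at ", prefix, " does not hold an epoch set", call. = FALSE)
  labels <- b$meta$labels
  if (length(labels) == 0L) labels <- NULL
  eeg_epochs(b$arrays$epochs, b$meta$fs, b$meta$window_s,
             b$arrays$start_times, labels, b$meta$channel_labels)
}
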