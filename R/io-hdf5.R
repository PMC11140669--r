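# Native persistence: HDF5 group "/ramanspec" with float64 datasets "axis"
# and "intensities" and group attributes "kind" and "format_version" ("1").
# Self-describing and streams large volumes.

.H5_GROUP <- "ramanspec"
.H5_FORMAT_VERSION <- "1"

#' Save a spectral container to the native HDF5 layout
#'
#' @param x A `spectral_container`.
#' @param path Output path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [load_container()]
#' @export
save_container <- function(x, path) {
  .assert_container(x)
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, .H5_GROUP)
  rhdf5::h5write(x$axis, path, file.path(.H5_GROUP, "axis"))
  rhdf5::h5write(x$intensities, path, file.path(.H5_GROUP, "intensities"))
  fid <- rhdf5::H5Fopen(path)
  gid <- rhdf5::H5Gopen(fid, .H5_GROUP)
  rhdf5::h5writeAttribute(x$kind, gid, "kind")
  rhdf5::h5writeAttribute(.H5_FORMAT_VERSION, gid, "format_version")
  rhdf5::H5Gclose(gid)
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' Load a spectral container from the native HDF5 layout
#'
#' @param path Path to a file written by [save_container()].
#' @return A `spectral_container`; the round trip is lossless (64-bit float
#'   intensities and axis, kind preserved).
#' @export
load_container <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  contents <- rhdf5::h5ls(path)
  if (!any(contents$name == .H5_GROUP)) {
    stop("format error: missing /ramanspec group", call. = FALSE)
  }
  attrs <- rhdf5::h5readAttributes(path, .H5_GROUP)
  ver <- as.character(attrs[["format_version"]])
  if (!identical(ver, .H5_FORMAT_VERSION)) {
    stop(sprintf("incompatible format_version '%s' (expected '%s')",
                 ver %||% "<missing>", .H5_FORMAT_VERSION), call. = FALSE)
  }
  for (ds in c("axis", "intensities")) {
    if (!any(contents$name == ds & contents$group == paste0("/", .H5_GROUP))) {
      stop(sprintf("format error: missing dataset '%s'", ds), call. = FALSE)
    }
  }
  axis <- as.numeric(rhdf5::h5read(path, file.path(.H5_GROUP, "axis")))
  intens <- rhdf5::h5read(path, file.path(.H5_GROUP, "intensities"))
  kind <- as.character(attrs[["kind"]])
  if (identical(kind, "spectrum")) intens <- as.numeric(intens)
  out <- spectral_container(intens, axis)
  if (!identical(out$kind, kind)) {
    stop(sprintf("format error: stored kind '%s' inconsistent with data (%s)",
                 kind, out$kind), call. = FALSE)
  }
  out
}
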