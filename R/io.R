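# File formats: the native volume format (raw little-endian array + text
# sidecar header), CSV batch/cloud export, and binary little-endian PLY
# point clouds.

#' Write and read volumes in the native raw + header format
#'
#' The volume is stored as a plain binary array (little-endian, C order with
#' the first index fastest) next to a flat text header recording `dims`,
#' `spacing`, `origin`, `dtype` (`float64` or `float32`), `byte_order`
#' (always `little`), and the data file name.
#'
#' @param volume A [voxel_volume()].
#' @param path Header file path; the array is written alongside with
#'   extension `.raw`.
#' @param dtype Storage type, `"float64"` (default) or `"float32"`.
#' @return `read_volume()` returns a [voxel_volume()].
#' @export
write_volume <- function(volume, path, dtype = c("float64", "float32")) {
  stopifnot(inherits(volume, "voxel_volume"))
  dtype <- match.arg(dtype)
  raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
  raw_path <- file.path(dirname(path), raw_name)
  num <- function(v) paste(sprintf("%.17g", v), collapse = ",")
  writeLines(c(sprintf("dims = %s", paste(volume$dims, collapse = ",")),
               sprintf("spacing = %s", num(volume$spacing)),
               sprintf("origin = %s", num(volume$origin)),
               sprintf("dtype = %s", dtype),
               "byte_order = little",
               sprintf("data_file = %s", raw_name)), path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$values), con,
           size = if (dtype == "float64") 8L else 4L, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  kv <- parse_flat_config(path)
  dims <- as.integer(strsplit(kv[["dims"]], ",")[[1]])
  spacing <- as.numeric(strsplit(kv[["spacing"]], ",")[[1]])
  origin <- as.numeric(strsplit(kv[["origin"]], ",")[[1]])
  if (!identical(unname(kv[["byte_order"]]), "little"))
    stop("only little-endian volumes are supported", call. = FALSE)
  size <- switch(unname(kv[["dtype"]]), float64 = 8L, float32 = 4L,
                 stop("unsupported dtype: ", kv[["dtype"]], call. = FALSE))
  raw_path <- file.path(dirname(path), kv[["data_file"]])
  con <- file(raw_path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "numeric", n = prod(dims), size = size,
                  endian = "little")
  voxel_volume(array(vals, dim = dims), spacing = spacing, origin = origin)
}

#' Read a NIfTI-1 volume
#'
#' Convenience ingest of a single NIfTI file through the RNifti package
#' (axis-aligned volumes; the pixel dimensions become the spacing and the
#' translational part of the stored transform the origin).
#'
#' @param path NIfTI file path.
#' @return A [voxel_volume()].
#' @export
read_volume_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  voxel_volume(array(as.numeric(img), dim = dim(img)),
               spacing = abs(diag(xf)[1:3]), origin = xf[1:3, 4])
}

#' Export a sample batch as CSV
#'
#' Columns `method`, `seed`, `y1`, `y2`, `x1`, `x2`, `px`, `py`, `pz`.
#'
#' @param batch A `sample_batch`.
#' @param path Output path.
#' @export
write_batch_csv <- function(batch, path) {
  stopifnot(is.data.frame(batch))
  readr::write_csv(tibble::as_tibble(batch)[, c("method", "seed", "y1", "y2",
                                                "x1", "x2", "px", "py", "pz")],
                   path)
  invisible(path)
}

#' Export a textured cloud as CSV
#'
#' Columns `x`, `y`, `z`, `gray`, `inside`.
#'
#' @param cloud A `textured_cloud` (or data frame with those fields).
#' @param path Output path.
#' @export
write_cloud_csv <- function(cloud, path) {
  stopifnot(is.data.frame(cloud))
  out <- tibble::tibble(x = cloud$px, y = cloud$py, z = cloud$pz,
                        gray = cloud$gray %||% NA_real_,
                        inside = cloud$inside %||% TRUE)
  readr::write_csv(out, path)
  invisible(path)
}

#' Export points as a binary PLY point cloud
#'
#' Binary little-endian PLY with float64 `x`, `y`, `z` vertex properties and,
#' when present, a float64 `gray` property.
#'
#' @param points A data frame with `px`, `py`, `pz` (or `x`, `y`, `z`) and
#'   optionally `gray`.
#' @param path Output path.
#' @export
write_ply <- function(points, path) {
  P <- points_matrix(points)
  has_gray <- "gray" %in% names(points)
  header <- c("ply", "format binary_little_endian 1.0",
              sprintf("element vertex %d", nrow(P)),
              "property double x", "property double y", "property double z",
              if (has_gray) "property double gray",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(header, collapse = "\n"), "\n"), con, eos = NULL)
  M <- if (has_gray) cbind(P, ifelse(is.na(points$gray), NaN, points$gray)) else P
  writeBin(as.numeric(t(M)), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a binary PLY point cloud written by [write_ply()]
#'
#' @param path PLY file path.
#' @return A tibble with columns `px`, `py`, `pz` and `gray` if present.
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (line == "end_header") break
  }
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", header, value = TRUE)))
  props <- sub("property double ", "", grep("^property", header, value = TRUE))
  M <- matrix(readBin(con, "numeric", n = nv * length(props), size = 8L,
                      endian = "little"),
              ncol = length(props), byrow = TRUE)
  out <- tibble::tibble(px = M[, 1], py = M[, 2], pz = M[, 3])
  if ("gray" %in% props) out$gray <- M[, which(props == "gray")]
  out
}
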