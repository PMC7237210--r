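# MDA binary array I/O.
#
# Dialect: little-endian; header is a sequence of 32-bit signed integers
# [type_code, bytes_per_element, ndim, dim_1, ..., dim_N]; payload is the dense
# array in column-major element order (the MountainSort convention, matching
# the deposited firings_true.mda files).

.mda_types <- data.frame(
  code  = c(-3L, -4L, -5L, -6L, -7L, -8L),
  name  = c("float32", "int16", "int32", "uint16", "float64", "uint32"),
  bytes = c(4L, 2L, 4L, 2L, 8L, 4L),
  stringsAsFactors = FALSE
)

.mda_type_info <- function(type) {
  if (is.numeric(type)) {
    row <- .mda_types[.mda_types$code == as.integer(type), ]
  } else {
    row <- .mda_types[.mda_types$name == type, ]
  }
  if (nrow(row) != 1L) {
    stop("unsupported MDA type: ", type, call. = FALSE)
  }
  row
}

#' Read an MDA binary array
#'
#' Reads the simple N-dimensional binary array format used for extracellular
#' timeseries and firing-event matrices. All payloads are little-endian and
#' column-major, so the result maps directly onto an R array.
#'
#' @param path Path to an `.mda` file.
#' @return A numeric array (matrix when 2-dimensional) with attribute
#'   `mda_type` giving the on-disk element type (`"float32"`, `"int16"`,
#'   `"int32"`, `"uint16"`, `"float64"` or `"uint32"`).
#' @seealso [write_mda()]
#' @export
read_mda <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))

  hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  if (length(hdr) < 3L) stop("MDA header truncated: ", path, call. = FALSE)
  info <- .mda_type_info(hdr[1L])
  if (hdr[2L] != info$bytes) {
    stop("MDA header inconsistent: type ", info$name, " declares ",
         hdr[2L], " bytes per element", call. = FALSE)
  }
  ndim <- hdr[3L]
  if (ndim < 1L) stop("MDA header declares ndim < 1", call. = FALSE)
  dims <- readBin(con, "integer", n = ndim, size = 4L, endian = "little")
  if (length(dims) < ndim || any(dims < 1L)) {
    stop("MDA header has missing or non-positive dimensions", call. = FALSE)
  }

  n <- prod(dims)
  x <- switch(info$name,
    float32 = readBin(con, "double", n = n, size = 4L, endian = "little"),
    float64 = readBin(con, "double", n = n, size = 8L, endian = "little"),
    int16   = readBin(con, "integer", n = n, size = 2L, signed = TRUE,
                      endian = "little"),
    uint16  = readBin(con, "integer", n = n, size = 2L, signed = FALSE,
                      endian = "little"),
    int32   = readBin(con, "integer", n = n, size = 4L, endian = "little"),
    uint32  = {
      # via raw bytes: R has no unsigned 32-bit readBin (and NA_integer_
      # collides with 2^31)
      raw_b <- readBin(con, "raw", n = n * 4L)
      nfull <- length(raw_b) %/% 4L
      b <- matrix(as.integer(raw_b[seq_len(nfull * 4L)]), nrow = 4L)
      b[1L, ] + 256 * b[2L, ] + 65536 * b[3L, ] + 16777216 * b[4L, ]
    }
  )
  if (length(x) < n) {
    stop("MDA payload truncated: expected ", n, " elements, got ",
         length(x), call. = FALSE)
  }
  out <- array(x, dim = dims)
  attr(out, "mda_type") <- info$name
  out
}

#' Write an MDA binary array
#'
#' @param x Numeric array or matrix.
#' @param path Output file path.
#' @param type Element type on disk; defaults to the array's `mda_type`
#'   attribute, else `"float64"` for doubles and `"int32"` for integers.
#' @return `path`, invisibly. Writing the same array twice produces
#'   byte-identical files.
#' @export
write_mda <- function(x, path, type = NULL) {
  if (is.null(dim(x))) dim(x) <- length(x)
  dims <- dim(x)
  if (length(dims) < 1L || any(dims < 1L)) {
    stop("array must have at least one positive dimension", call. = FALSE)
  }
  if (is.null(type)) {
    type <- attr(x, "mda_type")
    if (is.null(type)) type <- if (is.integer(x)) "int32" else "float64"
  }
  info <- .mda_type_info(type)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(info$code, info$bytes, length(dims), dims)),
           con, size = 4L, endian = "little")
  v <- as.vector(x)
  switch(info$name,
    float32 = writeBin(as.double(v), con, size = 4L, endian = "little"),
    float64 = writeBin(as.double(v), con, size = 8L, endian = "little"),
    int16   = writeBin(as.integer(v), con, size = 2L, endian = "little"),
    uint16  = writeBin(as.integer(v), con, size = 2L, endian = "little"),
    int32   = writeBin(as.integer(v), con, size = 4L, endian = "little"),
    uint32  = {
      # via raw bytes, for the same reason as in read_mda
      v <- round(v)
      b <- rbind(v %% 256, v %/% 256 %% 256, v %/% 65536 %% 256,
                 v %/% 16777216 %% 256)
      writeBin(as.raw(b), con)
    }
  )
  invisible(path)
}

#' SHA-1 content URI of a file
#'
#' Returns `sha1://<40-hex-digest>/<basename>`, the content-addressed URI
#' scheme used to make every input and output of an analysis reproducible:
#' the digest depends only on the file bytes, never on its location.
#'
#' @param path Path to an existing file.
#' @return A `sha1://` URI string.
#' @export
sha1_uri <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dg <- digest::digest(file = path, algo = "sha1")
  paste0("sha1://", dg, "/", basename(path))
}

#' Register a file in a local content store
#'
#' A minimal local stand-in for a networked content-addressable store: files
#' are copied into `store_dir` under their SHA-1 digest and can be resolved
#' back from a `sha1://` URI.
#'
#' @param path File to register.
#' @param store_dir Store directory (created if needed).
#' @return The file's `sha1://` URI.
#' @export
sha1_store_put <- function(path, store_dir) {
  uri <- sha1_uri(path)
  dg <- sub("^sha1://([0-9a-f]{40})/.*$", "\\1", uri)
  dir.create(store_dir, showWarnings = FALSE, recursive = TRUE)
  dest <- file.path(store_dir, dg)
  if (!file.exists(dest)) file.copy(path, dest)
  uri
}

#' Resolve a SHA-1 URI against a local content store
#'
#' @param uri A `sha1://<digest>/<name>` URI.
#' @param store_dir Store directory used by [sha1_store_put()].
#' @return Path to the stored file.
#' @export
sha1_store_get <- function(uri, store_dir) {
  if (!grepl("^sha1://[0-9a-f]{40}/", uri)) {
    stop("not a sha1 URI: ", uri, call. = FALSE)
  }
  dg <- sub("^sha1://([0-9a-f]{40})/.*$", "\\1", uri)
  dest <- file.path(store_dir, dg)
  if (!file.exists(dest)) stop("digest not in local store: ", dg, call. = FALSE)
  dest
}
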