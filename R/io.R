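#' Read and write connectivity matrices as CSV
#'
#' Dense square CSV with node ids as header row and first column. Values are
#' written with full precision (`%.17g`) so a write-read cycle is
#' bit-identical. On read the matrix must be square and symmetric within
#' 1e-9; violations are reported with the offending indices.
#'
#' @param x a [connectome()].
#' @param path file path.
#' @param kind weight kind for the object built on read; `"auto"` infers
#'   `"nos"` for all-integer matrices.
#' @return `read_connectome_csv` returns a [connectome()];
#'   `write_connectome_csv` returns `path` invisibly.
#' @export
write_connectome_csv <- function(x, path) {
  w <- x$weights
  header <- paste(c("node", x$nodes), collapse = ",")
  rows <- vapply(seq_len(nrow(w)), function(i)
    paste(c(x$nodes[i], sprintf("%.17g", w[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_connectome_csv
#' @export
read_connectome_csv <- function(path, kind = "auto") {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1,
                        colClasses = "character")
  m <- apply(as.matrix(df), c(1, 2), as.numeric)
  if (nrow(m) != ncol(m))
    stop_param(path, ": matrix is not square (", nrow(m), " x ", ncol(m), ")")
  if (!identical(rownames(m), colnames(m)))
    stop_param(path, ": row and column node ids differ")
  dev <- abs(m - t(m))
  if (max(dev) > 1e-9) {
    idx <- which(dev == max(dev), arr.ind = TRUE)[1, ]
    stop_param(sprintf(
      "%s: matrix asymmetric beyond 1e-9 at row %d (%s), column %d (%s)",
      path, idx[1], rownames(m)[idx[1]], idx[2], colnames(m)[idx[2]]))
  }
  integral <- max(abs(m - round(m))) <= 1e-9
  if (kind == "auto") kind <- if (integral) "nos" else "scalar"
  # non-integral NOS matrices arise as across-subject consensus medians
  prov <- if (kind == "nos" && !integral) list(consensus = TRUE) else list()
  connectome(m, kind, rownames(m), provenance = prov)
}

#' Read and write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving the voxel-to-world affine
#' (stored as sform/qform with code 2). `read_volume` returns a
#' [label_volume()] when the data are non-negative integers and
#' `as = "auto"`, otherwise a [scalar_volume()].
#'
#' @param vol a [scalar_volume()] or [label_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @param as `"auto"`, `"scalar"` or `"label"`.
#' @return `read_volume` returns a volume object; `write_volume` returns
#'   `path` invisibly.
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$grid * 1)
  img <- RNifti::`pixdim<-`(img, sqrt(colSums(vol$affine[1:3, 1:3]^2)))
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, as = "auto") {
  img <- RNifti::readNifti(path)
  grid <- array(as.array(img), dim = dim(img)) # strip image attributes
  if (length(dim(grid)) != 3) stop_param(path, ": expected a 3-D volume")
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  is_lab <- all(grid >= 0) && max(abs(grid - round(grid))) < 1e-6
  if (as == "label" || (as == "auto" && is_lab))
    label_volume(round(grid), affine)
  else scalar_volume(grid, affine)
}

#' Read and write MRtrix TCK tractograms
#'
#' Implements the MRtrix track file format: a text header
#' (`mrtrix tracks`, key-value lines, `file: . <offset>`, `END`) followed by
#' little-endian float32 vertex triplets, with NaN triplets separating
#' streamlines and an Inf triplet terminating the stream. TCK coordinates
#' are world mm, so no conversion is applied.
#'
#' @param t a [tractogram()].
#' @param path file path.
#' @return `read_tck` returns a [tractogram()]; `write_tck` returns `path`
#'   invisibly.
#' @export
write_tck <- function(t, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           sprintf("count: %d", length(t$streamlines)))
  # reserve room for the offset line, then fix it up
  offset_line <- function(off) sprintf("file: . %d", off)
  guess <- sum(nchar(hdr) + 1) + nchar("END\n") + nchar(offset_line(0)) + 1
  off <- guess
  for (i in 1:5) {
    new_off <- sum(nchar(hdr) + 1) + nchar(offset_line(off)) + 1 +
      nchar("END\n")
    if (new_off == off) break
    off <- new_off
  }
  writeChar(paste0(paste(c(hdr, offset_line(off)), collapse = "\n"),
                   "\nEND\n"),
            con, eos = NULL)
  for (s in t$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (!identical(rawToChar(raw[1:13]), "mrtrix tracks"))
    stop_param(path, ": not a TCK file (bad magic)")
  # header ends at the line 'END'
  txt_end <- NULL
  nl <- which(raw == as.raw(10))
  prev <- 0
  offset <- NULL
  dtype <- "Float32LE"
  for (p in nl) {
    line <- rawToChar(raw[(prev + 1):(p - 1)])
    prev <- p
    if (line == "END") { txt_end <- p; break }
    if (grepl("^file:", line))
      offset <- as.integer(sub("^file:\\s*\\.\\s*", "", line))
    if (grepl("^datatype:", line))
      dtype <- trimws(sub("^datatype:", "", line))
  }
  if (is.null(txt_end) || is.null(offset))
    stop_param(path, ": malformed TCK header")
  if (!dtype %in% c("Float32LE", "Float32BE"))
    stop_param(path, ": unsupported datatype ", dtype)
  endian <- if (dtype == "Float32LE") "little" else "big"
  body <- raw[(offset + 1):length(raw)]
  vals <- readBin(body, "numeric", n = length(body) / 4, size = 4,
                  endian = endian)
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  sls <- list()
  cur <- NULL
  for (r in seq_len(nrow(pts))) {
    p <- pts[r, ]
    if (any(is.infinite(p))) break
    if (any(is.nan(p))) {
      if (!is.null(cur)) sls[[length(sls) + 1]] <- do.call(rbind, cur)
      cur <- NULL
    } else cur <- c(cur, list(p))
  }
  if (!is.null(cur)) sls[[length(sls) + 1]] <- do.call(rbind, cur)
  tractogram(sls)
}

#' Read and write TrackVis TRK tractograms
#'
#' Implements the TrackVis format (1000-byte binary header, version 2).
#' TRK stores vertices in "voxel-mm" coordinates with the origin at the
#' corner of voxel (0,0,0); on read they are converted to world mm via
#' `world = vox_to_ras %*% (p / voxel_size - 0.5)`, and the inverse is
#' applied on write.
#'
#' @param t a [tractogram()] (world mm).
#' @param path file path.
#' @param affine voxel-to-world matrix stored in the header on write.
#' @param voxel_size voxel dimensions stored in the header on write.
#' @return `read_trk` returns a [tractogram()] in world mm; `write_trk`
#'   returns `path` invisibly.
#' @export
write_trk <- function(t, path, affine = diag(4),
                      voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))) {
  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(x, size, what = "numeric")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             con, size = size, endian = "little")
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(as.raw(0), con)
  wb(c(0, 0, 0), 2, "integer")              # dim (unused here)
  wb(voxel_size, 4)                          # voxel_size
  wb(c(0, 0, 0), 4)                          # origin
  wb(0, 2, "integer")                        # n_scalars
  writeBin(raw(200), con)                    # scalar names
  wb(0, 2, "integer")                        # n_properties
  writeBin(raw(200), con)                    # property names
  wb(as.numeric(t(affine)), 4)               # vox_to_ras, row-major
  writeBin(raw(444), con)                    # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)
  writeBin(raw(1), con)                      # voxel_order pad
  writeBin(raw(4), con)                      # pad2
  wb(rep(0, 6), 4)                           # image_orientation_patient
  writeBin(raw(2), con)                      # pad1
  writeBin(raw(6), con)                      # invert/swap flags
  wb(length(t$streamlines), 4, "integer")    # n_count
  wb(2, 4, "integer")                        # version
  wb(1000, 4, "integer")                     # hdr_size
  inv <- solve(affine)
  for (s in t$streamlines) {
    vox <- t(inv[1:3, 1:3] %*% t(s) + inv[1:3, 4]) # centre-based voxel
    trkmm <- sweep(vox + 0.5, 2, voxel_size, "*")
    wb(nrow(s), 4, "integer")
    wb(as.numeric(t(trkmm)), 4)
  }
  invisible(path)
}

#' @rdname write_trk
#' @export
read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 5, useBytes = TRUE)
  if (!identical(magic, "TRACK"))
    stop_param(path, ": not a TRK file (bad magic)")
  readBin(con, "raw", 1)
  readBin(con, "integer", 3, size = 2, endian = "little")       # dim
  voxel_size <- readBin(con, "numeric", 3, size = 4, endian = "little")
  readBin(con, "numeric", 3, size = 4, endian = "little")       # origin
  n_scalars <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  n_props <- readBin(con, "integer", 1, size = 2, endian = "little")
  readBin(con, "raw", 200)
  affine <- matrix(readBin(con, "numeric", 16, size = 4, endian = "little"),
                   4, 4, byrow = TRUE)
  readBin(con, "raw", 444 + 4 + 4 + 24 + 2 + 6)
  n_count <- readBin(con, "integer", 1, size = 4, endian = "little")
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (hdr_size != 1000)
    stop_param(path, ": malformed TRK header (hdr_size ", hdr_size, ")")
  if (version == 2 && all(affine == 0))
    stop_param(path, ": TRK v2 header has empty vox_to_ras")
  if (all(affine == 0)) affine <- diag(4)
  sls <- list()
  repeat {
    np <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(np) == 0) break
    vals <- readBin(con, "numeric", np * (3 + n_scalars), size = 4,
                    endian = "little")
    if (n_props > 0)
      readBin(con, "numeric", n_props, size = 4, endian = "little")
    pm <- matrix(vals, ncol = 3 + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pm, 2, voxel_size, "/") - 0.5
    sls[[length(sls) + 1]] <- t(affine[1:3, 1:3] %*% t(vox) + affine[1:3, 4])
  }
  if (n_count > 0 && length(sls) != n_count)
    warning(path, ": header announced ", n_count, " tracks, read ",
            length(sls))
  tractogram(sls)
}

#' Read a tractogram, dispatching on the file's magic bytes
#'
#' @param path a TCK or TRK file.
#' @return a [tractogram()] in world mm.
#' @export
read_tractogram <- function(path) {
  magic <- readBin(path, "raw", 13)
  if (length(magic) >= 13 && identical(rawToChar(magic[1:13]), "mrtrix tracks"))
    read_tck(path)
  else if (length(magic) >= 5 && identical(rawToChar(magic[1:5]), "TRACK"))
    read_trk(path)
  else stop_param(path, ": unrecognized tractogram format")
}

#' Read and write node class tables
#'
#' CSV with columns `node`, `functional`, `cyto`.
#'
#' @param classes class map data frame.
#' @param path file path.
#' @return `read_class_table` returns the data frame; `write_class_table`
#'   returns `path` invisibly.
#' @export
write_class_table <- function(classes, path) {
  utils::write.csv(classes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_class_table
#' @export
read_class_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("node", "functional", "cyto")
  if (!all(need %in% names(df)))
    stop_param(path, ": class table needs columns ",
               paste(need, collapse = ", "))
  df$node <- as.character(df$node)
  df
}
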