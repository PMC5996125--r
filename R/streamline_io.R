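#' Read and write streamline files
#'
#' Streamline bundles are stored as MRtrix `.tck` or TrackVis `.trk` files,
#' chosen by file extension. In both formats this package stores point
#' coordinates in world millimeters exactly as held in the [bundle()] —
#' the voxel/world ambiguity between tracking dialects is avoided by fixing
#' the world-mm convention package-wide. Single-precision storage bounds
#' the round-trip error at about 1e-4 mm for the coordinate magnitudes in
#' use here.
#'
#' @param bundle a [bundle()].
#' @param path output file, extension `.tck` or `.trk`.
#' @param voxel_size mm per axis recorded in the `.trk` header.
#' @param grid_shape grid dimensions recorded in the `.trk` header.
#' @return `write_streamlines` returns `path` invisibly; `read_streamlines`
#'   returns a [bundle()].
#' @name streamline_io
NULL

#' @rdname streamline_io
#' @export
write_streamlines <- function(bundle, path, voxel_size = c(1, 1, 1),
                              grid_shape = c(0L, 0L, 0L)) {
  stopifnot(inherits(bundle, "bundle"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = write_tck(bundle, path),
    trk = write_trk(bundle, path, voxel_size, grid_shape),
    stop("unsupported streamline format '.", ext, "' (use .tck or .trk)")
  )
  invisible(path)
}

#' @rdname streamline_io
#' @export
read_streamlines <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tck = read_tck(path),
    trk = read_trk(path),
    stop("unsupported streamline format '.", ext, "' (use .tck or .trk)")
  )
}

write_tck <- function(bundle, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("mrtrix tracks",
           "datatype: Float32LE",
           paste0("count: ", length(bundle$streamlines)),
           paste0("fascicle: ", bundle$provenance$fascicle),
           paste0("hemisphere: ", bundle$provenance$hemisphere),
           paste0("subject: ", bundle$provenance$subject))
  # the data offset counts the header itself, including the offset digits:
  # iterate to the fixed point (stable after <= 3 rounds)
  off <- 0L
  repeat {
    full <- paste0(paste(append(hdr, paste0("file: . ", off), after = 1L),
                         collapse = "\n"), "\nEND\n")
    if (nchar(full, type = "bytes") == off) break
    off <- nchar(full, type = "bytes")
  }
  writeChar(full, con, eos = NULL)
  for (p in bundle$streamlines) {
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
    writeBin(rep(NaN, 3L), con, size = 4L, endian = "little")
  }
  writeBin(rep(Inf, 3L), con, size = 4L, endian = "little")
}

read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character(0)
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0L) stop("malformed .tck header (no END)")
    if (trimws(l) == "END") break
    lines <- c(lines, l)
  }
  if (!identical(lines[1L], "mrtrix tracks")) stop("not a .tck file")
  kv <- strsplit(lines[-1L], ": ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ": "), ""))
  off <- as.integer(sub("^\\. ", "", vals[keys == "file"]))
  seek(con, off)
  raw <- readBin(con, "numeric", n = file.size(path), size = 4L,
                 endian = "little")
  m <- matrix(raw, ncol = 3L, byrow = TRUE)
  is_nan <- rowSums(is.na(m)) > 0
  is_inf <- rowSums(is.infinite(m)) > 0
  breaks <- which(is_nan | is_inf)
  sl <- list()
  start <- 1L
  for (b in breaks) {
    if (b > start) sl[[length(sl) + 1L]] <- m[start:(b - 1L), , drop = FALSE]
    start <- b + 1L
    if (is_inf[b]) break
  }
  grab <- function(key, default) {
    v <- vals[keys == key]
    if (length(v)) v[[1L]] else default
  }
  bundle(sl, name = tools::file_path_sans_ext(basename(path)),
         subject = grab("subject", "s1"),
         hemisphere = grab("hemisphere", "L"),
         fascicle = grab("fascicle", "whole"))
}

trk_chr <- function(s, width) {
  r <- charToRaw(s)
  c(r[seq_len(min(length(r), width))],
    raw(width - min(length(r), width)))
}

write_trk <- function(bundle, path, voxel_size, grid_shape) {
  con <- file(path, "wb")
  on.exit(close(con))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  writeBin(trk_chr("TRACK", 6L), con)
  writeBin(as.integer(rep_len(grid_shape, 3L)), con, size = 2L,
           endian = "little")
  writeBin(voxel_size, con, size = 4L, endian = "little")
  writeBin(numeric(3L), con, size = 4L, endian = "little")   # origin
  writeBin(0L, con, size = 2L, endian = "little")            # n_scalars
  writeBin(raw(200L), con)                                   # scalar names
  writeBin(0L, con, size = 2L, endian = "little")            # n_properties
  writeBin(raw(200L), con)                                   # property names
  m <- diag(4); m[1, 1] <- voxel_size[1]; m[2, 2] <- voxel_size[2]
  m[3, 3] <- voxel_size[3]
  writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  writeBin(raw(444L), con)                                   # reserved
  writeBin(trk_chr("RAS", 4L), con)                          # voxel_order
  writeBin(raw(4L), con)                                     # pad2
  writeBin(c(1, 0, 0, 0, 1, 0), con, size = 4L, endian = "little")
  writeBin(raw(2L), con)                                     # pad1
  writeBin(raw(6L), con)                                     # invert/swap
  writeBin(length(bundle$streamlines), con, size = 4L, endian = "little")
  writeBin(2L, con, size = 4L, endian = "little")            # version
  writeBin(1000L, con, size = 4L, endian = "little")         # hdr_size
  for (p in bundle$streamlines) {
    writeBin(nrow(p), con, size = 4L, endian = "little")
    writeBin(as.numeric(t(p)), con, size = 4L, endian = "little")
  }
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (!identical(rawToChar(magic[1:5]), "TRACK")) stop("not a .trk file")
  seek(con, 988L)
  n_count <- readBin(con, "integer", size = 4L, endian = "little")
  version <- readBin(con, "integer", size = 4L, endian = "little")
  hdr_size <- readBin(con, "integer", size = 4L, endian = "little")
  if (hdr_size != 1000L) stop("unexpected .trk header size: ", hdr_size)
  seek(con, 12L)
  # n_scalars / n_properties live at offsets 36 and 238
  seek(con, 36L)
  n_scalars <- readBin(con, "integer", size = 2L, endian = "little")
  seek(con, 238L)
  n_props <- readBin(con, "integer", size = 2L, endian = "little")
  seek(con, 1000L)
  sl <- list()
  repeat {
    np <- readBin(con, "integer", size = 4L, endian = "little")
    if (length(np) == 0L) break
    dat <- readBin(con, "numeric", n = np * (3L + n_scalars), size = 4L,
                   endian = "little")
    if (n_props > 0L)
      readBin(con, "numeric", n = n_props, size = 4L, endian = "little")
    m <- matrix(dat, ncol = 3L + n_scalars, byrow = TRUE)
    sl[[length(sl) + 1L]] <- m[, 1:3, drop = FALSE]
    if (n_count > 0L && length(sl) >= n_count) break
  }
  bundle(sl, name = tools::file_path_sans_ext(basename(path)))
}
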