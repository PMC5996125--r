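#' Multi-peak fiber-orientation field
#'
#' An orientation field stores, for every voxel of a 3-D grid, up to `K`
#' resolved fiber directions ("peaks", unit 3-vectors with sign-ambiguous
#' axes) together with a per-peak quantitative anisotropy (QA) scalar.
#' It is the substrate of the deterministic tracker.
#'
#' The coordinate convention used throughout the package: voxel indices are
#' 0-based and world coordinates in mm are `(index + 0.5) * voxel_size`
#' (voxel-center convention). In R code voxel arrays are of course indexed
#' 1-based; [voxel_of()] and [voxel_center()] convert.
#'
#' @param peaks numeric array of dimension `c(grid_shape, K, 3)`; unit
#'   vectors, or zero rows for absent peaks.
#' @param qa numeric array of dimension `c(grid_shape, K)`; QA per peak,
#'   `0` marks an absent peak.
#' @param voxel_size numeric length-3 (or scalar, recycled), mm per axis.
#' @return An object of class `orientation_field` with elements `peaks`,
#'   `qa`, `n_peaks` (per-voxel count of nonzero-QA peaks), `grid_shape`,
#'   `K` and `voxel_size`.
#' @export
orientation_field <- function(peaks, qa, voxel_size) {
  dp <- dim(peaks)
  dq <- dim(qa)
  if (length(dp) != 5L || dp[5] != 3L)
    stop("'peaks' must be a 5-D array [X, Y, Z, K, 3]")
  if (length(dq) != 4L || any(dq != dp[1:4]))
    stop("'qa' must be a 4-D array [X, Y, Z, K] matching 'peaks'")
  if (any(qa < 0)) stop("QA values must be >= 0")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(voxel_size <= 0)) stop("voxel_size must be positive")
  nrm2 <- sqrt(apply(peaks^2, 1:4, sum))
  present <- qa > 0
  if (any(abs(nrm2[present] - 1) > 1e-6))
    stop("all peaks with QA > 0 must be unit vectors (|v| = 1 within 1e-6)")
  structure(
    list(
      peaks = peaks,
      qa = qa,
      n_peaks = apply(present, 1:3, sum),
      grid_shape = as.integer(dp[1:3]),
      K = as.integer(dp[4]),
      voxel_size = voxel_size
    ),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat("<orientation_field> ", paste(x$grid_shape, collapse = " x "),
      " voxels @ ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm, K = ", x$K, "\n", sep = "")
  cat("  voxels with >= 1 peak: ", sum(x$n_peaks > 0),
      "; with >= 2 peaks: ", sum(x$n_peaks > 1), "\n", sep = "")
  invisible(x)
}

#' Voxel containing a world-coordinate point
#'
#' Maps mm positions to 0-based voxel indices by the floor rule
#' `floor(mm / voxel_size)`; a point lying exactly on a voxel boundary
#' belongs to the higher-index voxel (the floor of its scaled coordinate).
#'
#' @param point numeric length-3 mm position, or an n x 3 matrix.
#' @param voxel_size mm per axis.
#' @return Integer 0-based voxel indices (length 3 or n x 3).
#' @export
voxel_of <- function(point, voxel_size) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.matrix(point)) {
    idx <- floor(sweep(point, 2L, voxel_size, "/"))
    storage.mode(idx) <- "integer"
    idx
  } else {
    as.integer(floor(point / voxel_size))
  }
}

#' World coordinate of a voxel center
#'
#' @param index 0-based voxel index (length 3 or n x 3 matrix).
#' @param voxel_size mm per axis.
#' @return mm position(s) of the voxel center(s).
#' @export
voxel_center <- function(index, voxel_size) {
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.matrix(index)) sweep(index + 0.5, 2L, voxel_size, "*")
  else (index + 0.5) * voxel_size
}

in_grid <- function(idx0, grid_shape) {
  all(idx0 >= 0L) && all(idx0 < grid_shape)
}

#' Peaks at a world position
#'
#' Nearest-voxel lookup (no directional interpolation): returns the peak set
#' of the voxel containing `point` under the floor rule. Points outside the
#' grid yield an empty peak set, which a caller uses as a termination signal.
#'
#' @param field an [orientation_field()].
#' @param point length-3 mm position.
#' @return A list with `directions` (m x 3 matrix of unit vectors) and
#'   `qa` (length m); m = 0 when the voxel is empty or the point is outside
#'   the grid.
#' @export
peaks_at <- function(field, point) {
  idx0 <- voxel_of(point, field$voxel_size)
  if (!in_grid(idx0, field$grid_shape))
    return(list(directions = matrix(numeric(0), 0L, 3L), qa = numeric(0)))
  i <- idx0 + 1L
  m <- field$n_peaks[i[1], i[2], i[3]]
  if (m == 0L)
    return(list(directions = matrix(numeric(0), 0L, 3L), qa = numeric(0)))
  q <- field$qa[i[1], i[2], i[3], ]
  keep <- which(q > 0)
  dirs <- matrix(field$peaks[i[1], i[2], i[3], keep, ], length(keep), 3L)
  list(directions = dirs, qa = q[keep])
}

# Flattened [nvox, K*3] / [nvox, K] views used by the tracker's inner loop.
# Column k + K*(c-1) of the peak matrix holds component c of peak k.
flatten_field <- function(field) {
  nv <- prod(field$grid_shape)
  pk <- field$peaks
  dim(pk) <- c(nv, field$K * 3L)
  qa <- field$qa
  dim(qa) <- c(nv, field$K)
  list(pk = pk, qa = qa, np = as.vector(field$n_peaks))
}
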