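#' Bundle volume by voxel occupancy
#'
#' The volume of a bundle is the number of distinct voxels containing at
#' least one streamline point — streamline segments are sub-sampled at no
#' more than half the smallest voxel dimension so a segment cannot skip a
#' voxel — times the voxel volume, reported in milliliters. Set semantics:
#' duplicated streamlines do not increase the volume.
#'
#' @param bundle a [bundle()].
#' @param voxel_size mm per axis of the reference grid.
#' @param grid_shape optional grid extent; points outside are ignored.
#' @return An object of class `volume_report`: list with `bundle`,
#'   `voxel_count` and `volume_ml`.
#' @export
bundle_volume <- function(bundle, voxel_size, grid_shape = NULL) {
  stopifnot(inherits(bundle, "bundle"))
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  sub <- voxel_size[which.min(voxel_size)] / 2
  vox <- character(0)
  keys <- lapply(bundle$streamlines, function(p) {
    if (nrow(p) == 0L) return(character(0))
    if (nrow(p) > 1L) {
      seg <- sqrt(rowSums(diff(p)^2))
      nsub <- max(1L, ceiling(max(seg) / sub))
      if (nsub > 1L) {
        t <- seq(0, 1, length.out = nsub + 1L)
        n <- nrow(p)
        a <- p[rep(seq_len(n - 1L), each = length(t)), , drop = FALSE]
        b <- p[rep(2:n, each = length(t)), , drop = FALSE]
        p <- a + (b - a) * t
      }
    }
    idx0 <- voxel_of(p, voxel_size)
    if (!is.null(grid_shape)) {
      ok <- idx0[, 1] >= 0L & idx0[, 1] < grid_shape[1] &
            idx0[, 2] >= 0L & idx0[, 2] < grid_shape[2] &
            idx0[, 3] >= 0L & idx0[, 3] < grid_shape[3]
      idx0 <- idx0[ok, , drop = FALSE]
    }
    unique(paste(idx0[, 1], idx0[, 2], idx0[, 3]))
  })
  vox <- unique(unlist(keys))
  structure(
    list(bundle = bundle$name, voxel_count = length(vox),
         volume_ml = length(vox) * prod(voxel_size) / 1000),
    class = "volume_report"
  )
}

#' Volume lateralization index
#'
#' `LI = 2 * (volume_left - volume_right) / (volume_left + volume_right)`,
#' bounded in `[-2, 2]`; positive values indicate leftward dominance.
#'
#' @param volume_left,volume_right bundle volumes (ml), not both zero.
#' @return Dimensionless LI.
#' @export
laterality_index <- function(volume_left, volume_right) {
  if (volume_left < 0 || volume_right < 0) stop("volumes must be >= 0")
  tot <- volume_left + volume_right
  if (tot <= 0) stop("both volumes are zero; LI undefined")
  2 * (volume_left - volume_right) / tot
}

#' Summary statistics over a masked set of CI cells
#'
#' Mean, sample (n-1) standard deviation, median and nonzero count over an
#' explicit set of cells of a CI matrix. The cell mask is explicit because
#' summary conventions (e.g. whether all-zero columns are included) vary;
#' each reported statistic states its mask.
#'
#' @param table numeric CI matrix with row and column names.
#' @param cells either `"all"` (every cell) or a data frame / 2-column
#'   matrix of (row name, column name) pairs.
#' @return An object of class `ci_summary`: list with `mean`, `sd`,
#'   `median`, `n_nonzero`, `n_cells` and `cells`.
#' @export
summarize_ci <- function(table, cells = "all") {
  stopifnot(is.matrix(table))
  if (identical(cells, "all")) {
    cells <- expand.grid(row = rownames(table), col = colnames(table),
                         stringsAsFactors = FALSE)
  }
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L) stop("empty cell mask")
  bad <- !(cells[[1L]] %in% rownames(table)) |
         !(cells[[2L]] %in% colnames(table))
  if (any(bad)) stop("cell mask refers to nonexistent cells")
  x <- table[cbind(cells[[1L]], cells[[2L]])]
  structure(
    list(mean = mean(x), sd = stats::sd(x), median = stats::median(x),
         n_nonzero = sum(x > 0), n_cells = length(x), cells = cells),
    class = "ci_summary"
  )
}

#' @export
print.ci_summary <- function(x, ...) {
  cat(sprintf(
    "<ci_summary> %d cells: mean %.2f, SD %.2f, median %.2f, %d nonzero\n",
    x$n_cells, x$mean, x$sd, x$median, x$n_nonzero))
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' `t = (mean_a - mean_b) / sqrt(s2_a/n_a + s2_b/n_b)` with
#' Welch–Satterthwaite degrees of freedom. For `tails = 1` the p-value is
#' one-sided in the direction of the observed effect,
#' `P(T >= |t|)`; for `tails = 2` it is two-sided.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2; at least
#'   one with nonzero variance.
#' @param tails 1 or 2.
#' @return An object of class `welch_test`: list with `t`, `df`, `p`,
#'   `tails`, `mean_a`, `mean_b`.
#' @export
welch_t <- function(sample_a, sample_b, tails = 2L) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs n >= 2")
  if (!tails %in% c(1L, 2L)) stop("tails must be 1 or 2")
  na <- length(sample_a); nb <- length(sample_b)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va + vb <= 0) stop("both samples have zero variance")
  se2 <- va / na + vb / nb
  t <- (mean(sample_a) - mean(sample_b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p1 <- stats::pt(abs(t), df, lower.tail = FALSE)
  structure(
    list(t = t, df = df, p = if (tails == 2L) 2 * p1 else p1,
         tails = as.integer(tails),
         mean_a = mean(sample_a), mean_b = mean(sample_b)),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("<welch_test> t = %.3f, df = %.1f, p = %.4g (%d-sided)\n",
              x$t, x$df, x$p, x$tails))
  invisible(x)
}
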