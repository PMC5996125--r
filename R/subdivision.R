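#' Split a bundle into dorsal and ventral sub-fascicles
#'
#' Mechanizes the separation of a fascicle with a bifurcated posterior
#' termination pattern. For each streamline the posterior endpoint — the
#' endpoint on the far side of `posterior_plane` along `side` — is
#' extracted, and the endpoints are clustered into two groups by a
#' deterministic 1-D 2-means on the superior–inferior (z) coordinate,
#' initialized at the coordinate extremes. The cluster with the greater
#' mean z is the dorsal group. When the between-cluster gap is smaller than
#' `gap_threshold` (default two voxels) the split is declared degenerate
#' and the whole bundle is returned as ventral.
#'
#' Streamlines with neither endpoint beyond the plane keep their farther
#' endpoint as the posterior one; it is an error if no streamline reaches
#' beyond the plane at all.
#'
#' @param bundle a [bundle()].
#' @param posterior_plane a [plane_roa()] separating the posterior
#'   termination zone (normal axis usually y).
#' @param side `+1` if posterior lies at coordinates greater than the plane
#'   position, `-1` otherwise.
#' @param voxel_size mm per axis (sets the degeneracy gap threshold).
#' @param gap_threshold minimum dorsal–ventral center separation in mm for
#'   a non-degenerate split (default `2 * voxel_size[3]`).
#' @return An object of class `subdivision_result`: list with `dorsal` and
#'   `ventral` [bundle()]s (a partition of the input), `separation_gap`
#'   (mm) and `degenerate` (logical).
#' @export
split_dorsal_ventral <- function(bundle, posterior_plane, side = 1,
                                 voxel_size = 1,
                                 gap_threshold = NULL) {
  stopifnot(inherits(bundle, "bundle"), inherits(posterior_plane, "plane_roa"))
  if (length(bundle$streamlines) == 0L) stop("bundle is empty")
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (is.null(gap_threshold)) gap_threshold <- 2 * voxel_size[3]
  ax <- posterior_plane$axis
  pos <- posterior_plane$position

  ends <- t(vapply(bundle$streamlines, function(p) {
    e1 <- p[1L, ]; e2 <- p[nrow(p), ]
    if (side * (e1[ax] - pos) >= side * (e2[ax] - pos)) e1 else e2
  }, numeric(3)))
  beyond <- side * (ends[, ax] - pos) > 0
  if (!any(beyond))
    stop("no streamline endpoint lies beyond the posterior plane")

  z <- ends[, 3L]
  km <- two_means_1d(z)
  gap <- abs(diff(km$centers))
  dorsal_cluster <- which.max(km$centers)

  mk <- function(keep, tag) {
    b <- bundle
    b$streamlines <- bundle$streamlines[keep]
    b$provenance$fascicle <- tag
    b$name <- paste0(bundle$name, ".", tag)
    b
  }
  if (gap < gap_threshold) {
    return(structure(
      list(dorsal = mk(logical(length(z)), "dorsal"),
           ventral = mk(!logical(length(z)), "ventral"),
           separation_gap = gap, degenerate = TRUE),
      class = "subdivision_result"))
  }
  structure(
    list(dorsal = mk(km$cluster == dorsal_cluster, "dorsal"),
         ventral = mk(km$cluster != dorsal_cluster, "ventral"),
         separation_gap = gap, degenerate = FALSE),
    class = "subdivision_result"
  )
}

# Deterministic 1-D 2-means: centers initialized at min(x) and max(x),
# Lloyd iterations to convergence. Ties at equal distance go to the lower
# center, so the outcome is independent of input order.
two_means_1d <- function(x, max_iter = 100L) {
  c1 <- min(x); c2 <- max(x)
  cl <- integer(length(x))
  for (it in seq_len(max_iter)) {
    new_cl <- ifelse(abs(x - c2) < abs(x - c1), 2L, 1L)
    if (identical(new_cl, cl) && it > 1L) break
    cl <- new_cl
    if (any(cl == 1L)) c1 <- mean(x[cl == 1L])
    if (any(cl == 2L)) c2 <- mean(x[cl == 2L])
  }
  list(cluster = cl, centers = c(c1, c2))
}

#' @export
print.subdivision_result <- function(x, ...) {
  cat("<subdivision_result> dorsal: ", length(x$dorsal$streamlines),
      ", ventral: ", length(x$ventral$streamlines),
      ", gap: ", round(x$separation_gap, 2), " mm",
      if (x$degenerate) " (degenerate)", "\n", sep = "")
  invisible(x)
}
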