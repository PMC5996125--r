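#' Selection geometry
#'
#' Geometric regions used to extract a fascicle from a tracked whole-brain
#' bundle: a spherical ROI (e.g. anterior temporal white matter), a box ROI
#' (e.g. a coronal slab at the temporo-occipital junction), a plane region
#' of avoidance (e.g. the sagittal hemispheric midline), and arbitrary
#' voxel-mask exclusion regions standing in for the manual removal of
#' spurious fibers belonging to neighboring fiber systems.
#'
#' @param center,radius sphere center (mm) and radius (mm > 0).
#' @param min_corner,max_corner box corners in mm, `min_corner <
#'   max_corner` componentwise.
#' @param axis plane normal axis: 1 (x), 2 (y) or 3 (z).
#' @param position plane position along `axis` in mm.
#' @param thickness slab thickness in mm (>= 0; 0 = infinitely thin plane,
#'   membership by segment crossing).
#' @param mask logical voxel array (same grid frame as the field).
#' @param voxel_size mm per axis of the mask grid.
#' @param name region name.
#' @return A region object of class `sphere_roi`, `box_roi`, `plane_roa`
#'   or `mask_region` (all also `tract_region`).
#' @name regions
NULL

#' @rdname regions
#' @export
sphere_roi <- function(center, radius, name = "sphere") {
  stopifnot(radius > 0, length(center) == 3L)
  structure(list(name = name, center = as.numeric(center), radius = radius),
            class = c("sphere_roi", "tract_region"))
}

#' @rdname regions
#' @export
box_roi <- function(min_corner, max_corner, name = "box") {
  min_corner <- as.numeric(min_corner); max_corner <- as.numeric(max_corner)
  if (!all(min_corner < max_corner))
    stop("min_corner must be < max_corner componentwise")
  structure(list(name = name, min_corner = min_corner,
                 max_corner = max_corner),
            class = c("box_roi", "tract_region"))
}

#' @rdname regions
#' @export
plane_roa <- function(axis, position, thickness = 0, name = "plane") {
  stopifnot(axis %in% 1:3, thickness >= 0)
  structure(list(name = name, axis = as.integer(axis),
                 position = position, thickness = thickness),
            class = c("plane_roa", "tract_region"))
}

#' @rdname regions
#' @export
mask_region <- function(mask, voxel_size, name = "mask") {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  structure(list(name = name, mask = mask,
                 voxel_size = rep_len(as.numeric(voxel_size), 3L)),
            class = c("mask_region", "tract_region"))
}

# Streamline points plus segment midpoints: membership testing at a spatial
# resolution of half the step size, so thin regions between samples are
# still caught.
sampled_points <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(points)
  mid <- (points[-n, , drop = FALSE] + points[-1L, , drop = FALSE]) / 2
  rbind(points, mid)
}

#' Does a streamline pass through a region?
#'
#' `TRUE` iff any streamline point — or any segment, tested by sub-sampling
#' at half the step size and, for zero-thickness planes, by exact
#' segment-plane crossing — lies inside the region.
#'
#' @param points n x 3 matrix of streamline points in mm.
#' @param region a region from [sphere_roi()], [box_roi()], [plane_roa()]
#'   or [mask_region()].
#' @return logical scalar.
#' @export
passes_through <- function(points, region) {
  UseMethod("passes_through", region)
}

#' @export
passes_through.sphere_roi <- function(points, region) {
  p <- sampled_points(points)
  any(rowSums(sweep(p, 2L, region$center)^2) <= region$radius^2)
}

#' @export
passes_through.box_roi <- function(points, region) {
  p <- sampled_points(points)
  any(p[, 1] >= region$min_corner[1] & p[, 1] <= region$max_corner[1] &
      p[, 2] >= region$min_corner[2] & p[, 2] <= region$max_corner[2] &
      p[, 3] >= region$min_corner[3] & p[, 3] <= region$max_corner[3])
}

#' @export
passes_through.plane_roa <- function(points, region) {
  x <- points[, region$axis] - region$position
  if (any(abs(x) <= region$thickness / 2)) return(TRUE)
  # exact crossing test: consecutive samples on opposite sides
  n <- length(x)
  n > 1L && any(x[-n] * x[-1L] < 0)
}

#' @export
passes_through.mask_region <- function(points, region) {
  p <- sampled_points(points)
  idx0 <- voxel_of(p, region$voxel_size)
  gs <- dim(region$mask)
  keep <- idx0[, 1] >= 0L & idx0[, 1] < gs[1] &
          idx0[, 2] >= 0L & idx0[, 2] < gs[2] &
          idx0[, 3] >= 0L & idx0[, 3] < gs[3]
  if (!any(keep)) return(FALSE)
  idx0 <- idx0[keep, , drop = FALSE] + 1L
  any(region$mask[idx0])
}

#' Select streamlines by inclusion and exclusion regions
#'
#' Keeps exactly the streamlines that pass through all `include` regions
#' (two-ROI conjunction) and through none of the `exclude` regions
#' (regions of avoidance / exclusion masks). Streamlines are never
#' mutated; provenance is preserved; the result does not depend on region
#' or streamline order.
#'
#' @param bundle a [bundle()].
#' @param include non-empty list of inclusion regions.
#' @param exclude list of exclusion regions (may be empty).
#' @return A [bundle()] with the retained subset (warning when empty).
#' @export
select_streamlines <- function(bundle, include, exclude = list()) {
  stopifnot(inherits(bundle, "bundle"))
  if (inherits(include, "tract_region")) include <- list(include)
  if (inherits(exclude, "tract_region")) exclude <- list(exclude)
  if (length(include) == 0L) stop("'include' must not be empty")
  keep <- vapply(bundle$streamlines, function(pts) {
    all(vapply(include, function(r) passes_through(pts, r), logical(1))) &&
      !any(vapply(exclude, function(r) passes_through(pts, r), logical(1)))
  }, logical(1))
  if (!any(keep)) warning("selection returned an empty bundle")
  out <- bundle
  out$streamlines <- bundle$streamlines[keep]
  out
}
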