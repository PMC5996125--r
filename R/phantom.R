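#' @title Synthetic orientation-field phantoms
#' @description
#' The phantom generator builds multi-peak orientation-field volumes with the
#' structure a fascicle-level tractography analysis assumes: tube-like bundles
#' along smooth curved centerlines, an optional posterior bifurcation into
#' dorsal and ventral branches, a crossing bundle creating multi-peak voxels,
#' labeled termination regions at both ends, controllable left/right volume
#' asymmetry, and angular noise — together with analytic ground truth
#' (centerline-following streamlines, per-bundle volumes, region-pair
#' connectivity).
#' @name phantom
NULL

# Run code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Bundle specification
#'
#' Describes one tube-like fiber bundle: a smooth centerline (interpolated by
#' natural cubic splines through the control points so tangents vary
#' continuously), a tube radius, the QA value carried by the bundle's peak,
#' optional angular jitter, and an optional fork into two branch centerlines.
#'
#' @param name bundle name.
#' @param centerline numeric matrix (>= 2 rows x 3 columns) of control points
#'   in mm.
#' @param radius tube radius in mm (> 0).
#' @param qa quantitative anisotropy assigned to this bundle's peak (> 0).
#' @param angular_jitter_sd SD in degrees of the angular noise applied to
#'   each in-tube peak (>= 0).
#' @param branch_point optional position in `[0, 1]` (fraction of centerline
#'   arc length) where the centerline forks into two branches.
#' @param branches when `branch_point` is given: a list of two control-point
#'   matrices; each branch's first control point must equal the fork point
#'   (use [centerline_point()] to obtain it).
#' @param hemisphere `"L"`, `"R"`, or `NA` (e.g. a crossing bundle).
#' @return An object of class `bundle_spec`.
#' @export
bundle_spec <- function(name, centerline, radius, qa = 0.5,
                        angular_jitter_sd = 0, branch_point = NULL,
                        branches = NULL, hemisphere = NA_character_) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 3L)
    stop("centerline needs >= 2 control points x 3 coordinates")
  if (radius <= 0) stop("radius must be > 0")
  if (qa <= 0) stop("qa must be > 0")
  if (angular_jitter_sd < 0) stop("angular_jitter_sd must be >= 0")
  if (!is.null(branch_point)) {
    if (branch_point < 0 || branch_point > 1)
      stop("branch_point must lie in [0, 1]")
    if (is.null(branches) || length(branches) != 2L)
      stop("a forked bundle needs exactly 2 branch centerlines")
    fork <- centerline_point(centerline, branch_point)
    for (b in branches) {
      b <- as.matrix(b)
      if (max(abs(b[1L, ] - fork)) > 1e-6)
        stop("branch centerlines must share the fork point (first row = ",
             "centerline_point(centerline, branch_point))")
    }
  }
  structure(
    list(name = name, centerline = centerline, radius = radius, qa = qa,
         angular_jitter_sd = angular_jitter_sd, branch_point = branch_point,
         branches = if (!is.null(branches)) lapply(branches, as.matrix),
         hemisphere = hemisphere),
    class = "bundle_spec"
  )
}

# Natural cubic spline through control points, chord-length parameterized.
spline_path <- function(controls, spacing = 0.25) {
  s <- c(0, cumsum(sqrt(rowSums(diff(controls)^2))))
  if (nrow(controls) == 2L) {
    # two points: a straight segment (spline would be linear anyway)
    tt <- unique(c(seq(0, s[2L], by = spacing), s[2L]))
    d <- (controls[2L, ] - controls[1L, ]) / s[2L]
    pts <- outer(tt, d) + rep(controls[1L, ], each = length(tt))
    tan <- matrix(d, length(tt), 3L, byrow = TRUE)
    return(list(points = pts, tangents = tan, total = s[2L]))
  }
  fx <- stats::splinefun(s, controls[, 1L], method = "natural")
  fy <- stats::splinefun(s, controls[, 2L], method = "natural")
  fz <- stats::splinefun(s, controls[, 3L], method = "natural")
  tt <- unique(c(seq(0, s[length(s)], by = spacing), s[length(s)]))
  pts <- cbind(fx(tt), fy(tt), fz(tt))
  tan <- cbind(fx(tt, deriv = 1L), fy(tt, deriv = 1L), fz(tt, deriv = 1L))
  tan <- tan / sqrt(rowSums(tan^2))
  list(points = pts, tangents = tan, total = s[length(s)])
}

#' Point on a centerline at a fractional arc-length position
#'
#' @param centerline control-point matrix.
#' @param t position in `[0, 1]` (fraction of total arc length).
#' @return length-3 mm position on the interpolated curve.
#' @export
centerline_point <- function(centerline, t) {
  p <- spline_path(as.matrix(centerline), spacing = 0.05)
  s <- c(0, cumsum(sqrt(rowSums(diff(p$points)^2))))
  i <- which.min(abs(s - t * s[length(s)]))
  p$points[i, ]
}

# The full centerline paths of a bundle (1 path, or 2 through the fork).
bundle_centerlines <- function(spec) {
  if (is.null(spec$branch_point)) return(list(spec$centerline))
  cl <- spec$centerline
  s <- c(0, cumsum(sqrt(rowSums(diff(cl)^2))))
  s_fork <- spec$branch_point * s[length(s)]
  fork <- centerline_point(cl, spec$branch_point)
  trunk <- cl[s < s_fork - 1e-9, , drop = FALSE]
  trunk <- rbind(trunk, fork)
  lapply(spec$branches, function(b) {
    unname(rbind(trunk, b[-1L, , drop = FALSE]))
  })
}

#' Phantom configuration
#'
#' @param grid_shape integer length-3, grid size in voxels.
#' @param voxel_size mm per axis (scalar or length 3).
#' @param bundles list of [bundle_spec()]s (main bundles, one or more per
#'   hemisphere).
#' @param label_regions list of `list(name=, min_corner=, max_corner=)` axis-
#'   aligned boxes in mm defining termination labels; must be disjoint.
#' @param asymmetry left:right tube radius ratio; radii of `hemisphere ==
#'   "R"` bundles are divided by this value, so the left/right volume ratio
#'   scales as `asymmetry^2`.
#' @param crossing_bundle optional [bundle_spec()] intersecting a main bundle.
#' @param n_truth ground-truth streamlines generated per centerline path.
#' @param seed integer RNG seed; the phantom is bit-reproducible given the
#'   full configuration.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape, voxel_size, bundles, label_regions,
                           asymmetry = 1, crossing_bundle = NULL,
                           n_truth = 10L, seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  if (any(grid_shape < 1L)) stop("grid_shape must be positive")
  if (asymmetry < 0) stop("asymmetry must be >= 0")
  stopifnot(length(bundles) >= 1L, length(label_regions) >= 1L)
  structure(
    list(grid_shape = grid_shape,
         voxel_size = rep_len(as.numeric(voxel_size), 3L),
         bundles = bundles, label_regions = label_regions,
         asymmetry = asymmetry, crossing_bundle = crossing_bundle,
         n_truth = as.integer(n_truth), seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# Rasterize one bundle: voxels whose center lies within `radius` of any
# centerline path. Returns linear voxel indices, tangent at the nearest
# centerline sample, and the centerline paths used.
rasterize_bundle <- function(spec, radius, grid_shape, voxel_size) {
  spacing <- 0.25 * min(voxel_size)
  paths <- lapply(bundle_centerlines(spec), spline_path, spacing = spacing)
  samples <- do.call(rbind, lapply(paths, `[[`, "points"))
  tangents <- do.call(rbind, lapply(paths, `[[`, "tangents"))
  extent <- grid_shape * voxel_size
  lo <- apply(samples, 2L, min) - radius
  hi <- apply(samples, 2L, max) + radius
  if (any(lo < 0) || any(hi > extent))
    stop("bundle '", spec$name, "' extends outside the grid")
  nv <- prod(grid_shape)
  dist2 <- rep(Inf, nv)
  nearest <- integer(nv)
  r_vox <- ceiling(radius / voxel_size)
  off <- as.matrix(expand.grid(-r_vox[1]:r_vox[1], -r_vox[2]:r_vox[2],
                               -r_vox[3]:r_vox[3]))
  for (i in seq_len(nrow(samples))) {
    ctr <- voxel_of(samples[i, ], voxel_size)           # 0-based
    cand <- sweep(off, 2L, ctr, "+")
    keep <- cand[, 1] >= 0L & cand[, 1] < grid_shape[1] &
            cand[, 2] >= 0L & cand[, 2] < grid_shape[2] &
            cand[, 3] >= 0L & cand[, 3] < grid_shape[3]
    cand <- cand[keep, , drop = FALSE]
    cc <- voxel_center(cand, voxel_size)
    d2 <- (cc[, 1] - samples[i, 1])^2 + (cc[, 2] - samples[i, 2])^2 +
          (cc[, 3] - samples[i, 3])^2
    lin <- cand[, 1] + grid_shape[1] * (cand[, 2] + grid_shape[2] * cand[, 3]) + 1L
    upd <- d2 < dist2[lin]
    dist2[lin[upd]] <- d2[upd]
    nearest[lin[upd]] <- i
  }
  in_tube <- which(dist2 <= radius^2)
  list(voxels = in_tube, tangents = tangents[nearest[in_tube], , drop = FALSE],
       paths = paths)
}

# Rotate unit rows of `v` by angles ~ N(0, sd_deg) about random axes
# perpendicular to each row (isotropic angular jitter).
jitter_directions <- function(v, sd_deg) {
  if (sd_deg <= 0 || nrow(v) == 0L) return(v)
  n <- nrow(v)
  u <- matrix(stats::rnorm(3L * n), n, 3L)
  u <- u - v * rowSums(u * v)              # project out the peak direction
  nrm <- sqrt(rowSums(u^2))
  nrm[nrm < 1e-12] <- 1
  u <- u / nrm
  th <- stats::rnorm(n, 0, sd_deg * pi / 180)
  out <- cos(th) * v + sin(th) * u
  out / sqrt(rowSums(out^2))
}

#' Generate a synthetic phantom dataset
#'
#' Builds the orientation field (one unit peak per bundle per in-tube voxel,
#' tangent to the local centerline, optionally jittered; QA equal to the
#' bundle's `qa` value and 0 outside all tubes), the integer label atlas,
#' per-bundle ground-truth streamlines and volumes, per-bundle membership
#' masks, and the ground-truth region-pair connectivity table.
#'
#' Voxels inside several tubes carry one peak per bundle, up to `K = 3`;
#' more than 3 overlapping bundles is a configuration error. Two calls with
#' the same configuration (including `seed`) produce bit-identical output.
#'
#' @param config a [phantom_config()].
#' @return An object of class `phantom_dataset`: a list with `field`
#'   ([orientation_field()]), `atlas` ([region_atlas()]), `truth_streamlines`
#'   (per bundle: a list of streamline point matrices, names carrying the
#'   branch index), `truth_volumes` (named, ml), `bundle_masks` (per bundle:
#'   logical voxel array), `truth_connectivity` (data frame), and `config`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  with_seed(config$seed, generate_phantom_impl(config))
}

generate_phantom_impl <- function(config) {
  gs <- config$grid_shape; vs <- config$voxel_size; K <- 3L
  peaks <- array(0, dim = c(gs, K, 3L))
  qa <- array(0, dim = c(gs, K))
  slot <- array(0L, dim = gs)

  all_bundles <- config$bundles
  if (!is.null(config$crossing_bundle))
    all_bundles <- c(all_bundles, list(config$crossing_bundle))

  truth_streamlines <- list()
  truth_volumes <- numeric(0)
  bundle_masks <- list()

  for (spec in all_bundles) {
    radius <- spec$radius
    if (identical(spec$hemisphere, "R")) {
      if (config$asymmetry == 0) stop("asymmetry 0 leaves no right bundle")
      radius <- radius / config$asymmetry
    }
    ras <- rasterize_bundle(spec, radius, gs, vs)
    if (length(ras$voxels) == 0L)
      stop("bundle '", spec$name, "' occupies no voxels")
    if (any(slot[ras$voxels] >= K))
      stop("more than ", K, " bundles overlap in at least one voxel")
    dirs <- jitter_directions(ras$tangents, spec$angular_jitter_sd)
    idx0 <- arrayInd(ras$voxels, gs)
    k <- slot[ras$voxels] + 1L
    for (cc in 1:3)
      peaks[cbind(idx0, k, cc)] <- dirs[, cc]
    qa[cbind(idx0, k)] <- spec$qa
    slot[ras$voxels] <- k

    msk <- array(FALSE, dim = gs)
    msk[ras$voxels] <- TRUE
    bundle_masks[[spec$name]] <- msk
    truth_volumes[[spec$name]] <- length(ras$voxels) * prod(vs) / 1000

    sl <- list()
    for (pi in seq_along(ras$paths)) {
      path <- ras$paths[[pi]]
      keep <- seq(1L, nrow(path$points),
                  by = max(1L, round(0.5 / (0.25 * min(vs)))))
      if (keep[length(keep)] != nrow(path$points))
        keep <- c(keep, nrow(path$points))
      base_pts <- path$points[keep, , drop = FALSE]
      base_tan <- path$tangents[keep, , drop = FALSE]
      for (j in seq_len(config$n_truth)) {
        o <- stats::rnorm(3L)
        o <- o / sqrt(sum(o^2)) * stats::runif(1, 0, 0.6 * radius)
        off <- matrix(o, nrow(base_pts), 3L, byrow = TRUE)
        off <- off - base_tan * rowSums(off * base_tan)
        sl[[length(sl) + 1L]] <- base_pts + off
      }
      names(sl)[(length(sl) - config$n_truth + 1L):length(sl)] <-
        paste0(spec$name, ".branch", pi, ".", seq_len(config$n_truth))
    }
    truth_streamlines[[spec$name]] <- sl
  }

  atlas <- rasterize_labels(config$label_regions, gs, vs)
  field <- orientation_field(peaks, qa, vs)
  ds <- structure(
    list(field = field, atlas = atlas,
         truth_streamlines = truth_streamlines,
         truth_volumes = truth_volumes, bundle_masks = bundle_masks,
         truth_connectivity = NULL, config = config),
    class = "phantom_dataset"
  )
  ds$truth_connectivity <- ground_truth_connectivity(ds)
  ds
}

# Boxes -> integer label volume; overlap is a configuration error.
rasterize_labels <- function(regions, grid_shape, voxel_size) {
  vol <- array(0L, dim = grid_shape)
  names <- character(length(regions))
  ax <- lapply(1:3, function(a)
    ((seq_len(grid_shape[a]) - 0.5) * voxel_size[a]))
  for (li in seq_along(regions)) {
    r <- regions[[li]]
    names[li] <- r$name
    ix <- lapply(1:3, function(a)
      which(ax[[a]] >= r$min_corner[a] & ax[[a]] <= r$max_corner[a]))
    if (any(lengths(ix) == 0L))
      stop("label region '", r$name, "' covers no voxels")
    sub <- vol[ix[[1]], ix[[2]], ix[[3]]]
    if (any(sub != 0L))
      stop("label regions overlap ('", r$name, "' and '",
           names[sub[sub != 0L][1L]], "')")
    vol[ix[[1]], ix[[2]], ix[[3]]] <- li
  }
  region_atlas(vol, names, voxel_size)
}

#' Ground-truth region-pair connectivity of a phantom
#'
#' Counts each ground-truth streamline once under the same endpoint
#' assignment rule as [count_matrix()] (voxel label, else nearest nonzero
#' label within the assignment radius). Endpoints that remain unlabeled are
#' reported in an explicit `"unassigned"` bin, never dropped.
#'
#' @param dataset a `phantom_dataset`.
#' @param radius endpoint assignment radius in voxels (default 2).
#' @return data frame with columns `bundle`, `region_a`, `region_b`, `count`
#'   (unordered pairs, `region_a <= region_b` alphabetically).
#' @export
ground_truth_connectivity <- function(dataset, radius = 2) {
  out <- list()
  for (bn in names(dataset$truth_streamlines)) {
    sl <- dataset$truth_streamlines[[bn]]
    if (length(sl) == 0L) next
    labs <- vapply(sl, function(pts) {
      a <- assign_endpoint(pts[1L, ], dataset$atlas, radius)
      b <- assign_endpoint(pts[nrow(pts), ], dataset$atlas, radius)
      pr <- sort(c(a, b))
      paste(pr, collapse = "\r")
    }, character(1))
    tab <- table(labs)
    pr <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    out[[bn]] <- data.frame(bundle = bn, region_a = pr[, 1L],
                            region_b = pr[, 2L],
                            count = as.integer(tab), row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse multi-peak voxels to a single averaged peak
#'
#' Produces a deliberately degraded field in which every voxel carries at
#' most one direction: the QA-weighted, sign-aligned mean of its peaks
#' (renormalized), with the maximum QA. This mimics a single-fiber (tensor-
#' like) model that cannot represent crossings, and is used to demonstrate
#' that multi-peak propagation is load-bearing.
#'
#' @param field an [orientation_field()].
#' @return An [orientation_field()] with `n_peaks <= 1` everywhere.
#' @export
degrade_to_single_peak <- function(field) {
  gs <- field$grid_shape; K <- field$K
  peaks <- array(0, dim = c(gs, K, 3L))
  qa <- array(0, dim = c(gs, K))
  multi <- which(field$n_peaks >= 1L)
  idx0 <- arrayInd(multi, gs)
  for (r in seq_len(nrow(idx0))) {
    i <- idx0[r, ]
    q <- field$qa[i[1], i[2], i[3], ]
    keep <- which(q > 0)
    P <- matrix(field$peaks[i[1], i[2], i[3], keep, ], length(keep), 3L)
    ref <- P[1L, ]
    sgn <- sign(P %*% ref)
    sgn[sgn == 0] <- 1
    m <- colSums(P * as.vector(sgn) * q[keep])
    nm <- sqrt(sum(m^2))
    if (nm < 1e-12) { m <- ref; nm <- 1 }
    peaks[i[1], i[2], i[3], 1L, ] <- m / nm
    qa[i[1], i[2], i[3], 1L] <- max(q[keep])
  }
  orientation_field(peaks, qa, field$voxel_size)
}
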