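#' Tracking parameters
#'
#' Parameters of the deterministic generalized-streamline tracker. The
#' defaults follow common deterministic multi-fiber practice: 0.2 mm step,
#' 60 degree turning-angle threshold, 20 mm minimum tract length, a
#' directional estimate blending 20% of the incoming direction with 80% of
#' the selected fiber orientation, and a QA termination threshold of 0.05
#' (midpoint of the commonly tuned 0.02–0.08 per-dataset range).
#'
#' @param step_size step length in mm.
#' @param angle_threshold maximum turning angle in degrees (0, 90).
#' @param qa_threshold QA below which propagation terminates.
#' @param w_incoming weight of the incoming direction in the directional
#'   blend; the selected peak receives `1 - w_incoming`.
#' @param min_length minimum accepted streamline length in mm.
#' @param max_streamlines cap on accepted streamlines per bundle.
#' @param max_steps cap on steps per half-track (guards termination).
#' @return An object of class `tracking_params`.
#' @export
tracking_params <- function(step_size = 0.2, angle_threshold = 60,
                            qa_threshold = 0.05, w_incoming = 0.2,
                            min_length = 20, max_streamlines = 100000L,
                            max_steps = 10000L) {
  if (step_size <= 0) stop("step_size must be > 0")
  if (angle_threshold <= 0 || angle_threshold >= 90)
    stop("angle_threshold must lie in (0, 90) degrees")
  if (qa_threshold <= 0) stop("qa_threshold must be > 0")
  if (w_incoming < 0 || w_incoming > 1) stop("w_incoming must be in [0, 1]")
  structure(
    list(step_size = step_size, angle_threshold = angle_threshold,
         qa_threshold = qa_threshold, w_incoming = w_incoming,
         w_peak = 1 - w_incoming, min_length = min_length,
         max_streamlines = as.integer(max_streamlines),
         max_steps = as.integer(max_steps)),
    class = "tracking_params"
  )
}

#' Bundle of streamlines
#'
#' A named set of streamlines with provenance (subject, hemisphere,
#' fascicle tag). Each streamline is an n x 3 matrix of mm positions with
#' constant inter-point spacing equal to the tracking step size.
#'
#' @param streamlines list of n x 3 point matrices.
#' @param name bundle name.
#' @param subject subject identifier.
#' @param hemisphere `"L"`, `"R"` or `"LR"` (merged).
#' @param fascicle `"whole"`, `"dorsal"` or `"ventral"`.
#' @return An object of class `bundle`.
#' @export
bundle <- function(streamlines, name = "bundle", subject = "s1",
                   hemisphere = "L", fascicle = "whole") {
  stopifnot(is.list(streamlines))
  structure(
    list(name = name, streamlines = streamlines,
         provenance = list(subject = subject, hemisphere = hemisphere,
                           fascicle = fascicle)),
    class = "bundle"
  )
}

#' @export
print.bundle <- function(x, ...) {
  len <- streamline_lengths(x)
  cat("<bundle> '", x$name, "': ", length(x$streamlines),
      " streamlines (", x$provenance$subject, ", ",
      x$provenance$hemisphere, ", ", x$provenance$fascicle, ")\n", sep = "")
  if (length(len))
    cat("  length [mm]: min ", round(min(len), 1), ", median ",
        round(stats::median(len), 1), ", max ", round(max(len), 1), "\n",
        sep = "")
  invisible(x)
}

#' @export
length.bundle <- function(x) length(x$streamlines)

#' Streamline lengths of a bundle
#' @param bundle a [bundle()].
#' @return numeric vector of polyline lengths in mm.
#' @export
streamline_lengths <- function(bundle) {
  vapply(bundle$streamlines, function(p) {
    if (nrow(p) < 2L) 0 else sum(sqrt(rowSums(diff(p)^2)))
  }, numeric(1))
}

#' Select the fiber orientation most congruent with the incoming direction
#'
#' Among candidate peaks with QA at or above the threshold, each considered
#' in both signs (peaks are axes), returns the sign-resolved direction
#' maximizing the dot product with the incoming direction — provided the
#' turning angle is below the angle threshold. Ties are broken by the lowest
#' peak index. Returns `NULL` when no admissible orientation exists
#' (termination signal).
#'
#' @param incoming unit 3-vector, the previous moving direction.
#' @param directions m x 3 matrix of candidate unit vectors.
#' @param qa length-m QA values of the candidates.
#' @param params a [tracking_params()].
#' @return Sign-resolved unit 3-vector, or `NULL`.
#' @export
select_orientation <- function(incoming, directions, qa, params) {
  if (is.null(dim(directions)))
    directions <- matrix(directions, ncol = 3L)
  ok <- which(qa >= params$qa_threshold)
  if (length(ok) == 0L) return(NULL)
  d <- directions[ok, , drop = FALSE] %*% incoming
  ad <- abs(d)
  best <- which.max(ad)                    # first maximum = lowest peak index
  if (ad[best] <= cos(params$angle_threshold * pi / 180)) return(NULL)
  s <- if (d[best] < 0) -1 else 1
  directions[ok[best], ] * s
}

#' Blend the incoming direction with the selected fiber orientation
#'
#' The next moving direction is the renormalized weighted sum
#' `w_incoming * incoming + (1 - w_incoming) * chosen`. Because the chosen
#' orientation is sign-aligned with the incoming direction (angle < 90
#' degrees), the blend never vanishes and its angle to the incoming
#' direction never exceeds the chosen orientation's.
#'
#' @param incoming unit 3-vector.
#' @param chosen unit 3-vector, sign-aligned with `incoming`.
#' @param params a [tracking_params()].
#' @return Unit 3-vector.
#' @export
step_direction <- function(incoming, chosen, params) {
  v <- params$w_incoming * incoming + params$w_peak * chosen
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(NULL)
  v / n
}

# One half-track from `pos` along `dir`; returns the positions visited
# (excluding the seed). Flat field views from flatten_field().
half_track <- function(fv, gs, vs, pos, dir, params) {
  K <- ncol(fv$qa)
  cos_thr <- cos(params$angle_threshold * pi / 180)
  pts <- matrix(0, params$max_steps, 3L)
  n <- 0L
  for (step in seq_len(params$max_steps)) {
    pos <- pos + params$step_size * dir
    i0 <- floor(pos / vs)
    if (i0[1] < 0 || i0[2] < 0 || i0[3] < 0 ||
        i0[1] >= gs[1] || i0[2] >= gs[2] || i0[3] >= gs[3]) break
    v <- (i0[1] + gs[1] * (i0[2] + gs[2] * i0[3])) + 1
    m <- fv$np[v]
    if (m == 0L) break
    q <- fv$qa[v, ]
    ok <- which(q >= params$qa_threshold)
    if (length(ok) == 0L) break
    P <- matrix(fv$pk[v, ], K, 3L)[ok, , drop = FALSE]
    d <- P %*% dir
    ad <- abs(d)
    b <- which.max(ad)
    if (ad[b] <= cos_thr) break
    chosen <- P[b, ] * (if (d[b] < 0) -1 else 1)
    nd <- params$w_incoming * dir + params$w_peak * chosen
    dir <- nd / sqrt(sum(nd^2))
    n <- n + 1L
    pts[n, ] <- pos
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Propagate one streamline from a seed point
#'
#' Tracks bidirectionally: two half-tracks are advanced along the positive
#' and negative sense of the seed voxel's best admissible peak, each moving
#' `step_size` mm per step along the blended direction (see
#' [step_direction()]), and are joined at the seed. A half-track terminates
#' when the next position leaves the grid, its voxel holds no peak with QA
#' at or above `qa_threshold`, no orientation is congruent within the
#' turning-angle threshold, or `max_steps` is reached. The joined tract is
#' accepted only if its length reaches `min_length`.
#'
#' @param field an [orientation_field()].
#' @param seed length-3 mm position.
#' @param params a [tracking_params()].
#' @return n x 3 matrix of points, or `NULL` when no streamline is accepted.
#' @export
propagate <- function(field, seed, params = tracking_params()) {
  propagate_flat(flatten_field(field), field$grid_shape, field$voxel_size,
                 seed, params)
}

propagate_flat <- function(fv, gs, vs, seed, params) {
  i0 <- floor(seed / vs)
  if (any(i0 < 0) || any(i0 >= gs)) return(NULL)
  v <- (i0[1] + gs[1] * (i0[2] + gs[2] * i0[3])) + 1
  if (fv$np[v] == 0L) return(NULL)
  q <- fv$qa[v, ]
  ok <- which(q >= params$qa_threshold)
  if (length(ok) == 0L) return(NULL)
  K <- ncol(fv$qa)
  P <- matrix(fv$pk[v, ], K, 3L)
  d0 <- P[ok[which.max(q[ok])], ]
  fwd <- half_track(fv, gs, vs, seed, d0, params)
  bwd <- half_track(fv, gs, vs, seed, -d0, params)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(seed, 1L, 3L), fwd)
  if ((nrow(pts) - 1L) * params$step_size < params$min_length) return(NULL)
  pts
}

#' Track a bundle from a stream of seed points
#'
#' Runs [propagate()] over the seeds in order, accumulating accepted
#' streamlines until the seed stream is exhausted or `max_streamlines` have
#' been accepted. Deterministic given the seed matrix and parameters.
#'
#' @param field an [orientation_field()].
#' @param seeds n x 3 matrix of seed positions in mm (see
#'   [seeds_from_mask()] / [random_seeds()]).
#' @param params a [tracking_params()].
#' @param name,subject,hemisphere,fascicle bundle provenance.
#' @return A [bundle()]; empty (with a warning) when no seed yields an
#'   accepted streamline.
#' @export
track_bundle <- function(field, seeds, params = tracking_params(),
                         name = "tracked", subject = "s1", hemisphere = "L",
                         fascicle = "whole") {
  seeds <- matrix(as.numeric(seeds), ncol = 3L)
  fv <- flatten_field(field)
  gs <- field$grid_shape; vs <- field$voxel_size
  out <- vector("list", min(nrow(seeds), params$max_streamlines))
  n <- 0L
  for (i in seq_len(nrow(seeds))) {
    if (n >= params$max_streamlines) break
    sl <- propagate_flat(fv, gs, vs, seeds[i, ], params)
    if (!is.null(sl)) {
      n <- n + 1L
      out[[n]] <- sl
    }
  }
  if (n == 0L) warning("no seed produced an accepted streamline")
  bundle(out[seq_len(n)], name = name, subject = subject,
         hemisphere = hemisphere, fascicle = fascicle)
}

#' Seed points from a voxel mask
#'
#' One seed per `TRUE` voxel (at the voxel center), optionally subsampled.
#' Voxel order (column-major) fixes the seed order, so seeding is
#' deterministic.
#'
#' @param mask logical voxel array.
#' @param voxel_size mm per axis.
#' @param every keep every `every`-th mask voxel (default 1 = all).
#' @return n x 3 matrix of mm positions.
#' @export
seeds_from_mask <- function(mask, voxel_size, every = 1L) {
  idx <- which(mask)
  if (every > 1L) idx <- idx[seq(1L, length(idx), by = every)]
  voxel_center(arrayInd(idx, dim(mask)) - 1L, voxel_size)
}

#' Random seed points within the supported voxels of a field
#'
#' Samples `n` voxels (with replacement) among those holding at least one
#' peak with QA at or above `qa_min`, then a uniform position inside each
#' voxel. Reproducible via `seed`.
#'
#' @param field an [orientation_field()].
#' @param n number of seeds.
#' @param seed RNG seed.
#' @param qa_min minimum QA for a voxel to be seedable.
#' @return n x 3 matrix of mm positions.
#' @export
random_seeds <- function(field, n, seed = 1L, qa_min = 0.05) {
  ok <- which(apply(field$qa, 1:3, max) >= qa_min)
  if (length(ok) == 0L) stop("no seedable voxels")
  with_seed(seed, {
    vox <- ok[sample.int(length(ok), n, replace = TRUE)]
    idx0 <- arrayInd(vox, field$grid_shape) - 1L
    u <- matrix(stats::runif(3L * n), n, 3L)
    sweep((idx0 + u), 2L, field$voxel_size, "*")
  })
}
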