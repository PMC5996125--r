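#' Standard phantom configurations
#'
#' Three ready-made [phantom_config()]s used throughout the package's tests
#' and examples:
#'
#' * `tube_phantom_config()` — a single straight tube along the y axis with
#'   one termination label at each end; the simplest tracking substrate and
#'   the analytic-volume reference (a cylinder of radius `radius` and
#'   centerline length `length`).
#' * `asymmetric_tube_pair_config()` — two parallel straight tubes, one per
#'   hemisphere, with the right radius scaled down by `asymmetry`; the
#'   cleanest substrate for volume-lateralization recovery.
#' * `crossing_phantom_config()` — two orthogonal straight tubes crossing at
#'   the grid center; voxels in the geometric intersection carry two peaks.
#'   Used to show that multi-peak propagation resolves crossings.
#' * `ilf_phantom_config()` — a two-hemisphere phantom emulating a ventral
#'   temporo-occipital association bundle: one curved tube per hemisphere
#'   running anterior to posterior, forking posteriorly into a dorsal and a
#'   ventral branch, with an anterior temporal label and two posterior
#'   occipital labels per hemisphere, controllable left/right volume
#'   asymmetry, and an optional orthogonal crossing bundle through the left
#'   tube.
#'
#' Axes follow the package convention x = left-right, y = anterior-posterior,
#' z = inferior-superior. The default `asymmetry` of 1.17 yields an analytic
#' volume-lateralization index of about 0.31, a realistic leftward dominance
#' for ventral association tracts.
#'
#' @param length tube centerline length in mm.
#' @param radius tube radius in mm.
#' @param voxel_size mm per axis.
#' @param jitter_sd angular noise SD in degrees.
#' @param qa QA value inside the tubes.
#' @param asymmetry left:right radius ratio (right radii are divided by it).
#' @param crossing add an orthogonal crossing bundle through the left tube.
#' @param n_truth ground-truth streamlines per centerline path.
#' @param seed RNG seed.
#' @return A [phantom_config()].
#' @name phantom_configs
NULL

#' @rdname phantom_configs
#' @export
tube_phantom_config <- function(length = 40, radius = 2, voxel_size = 1,
                                jitter_sd = 0, qa = 0.5, n_truth = 10L,
                                seed = 1L) {
  y0 <- 12
  y1 <- y0 + length
  margin <- radius + 6
  cl <- rbind(c(10, y0, 10), c(10, y1, 10))
  phantom_config(
    grid_shape = c(20L, ceiling(y1 + margin), 20L),
    voxel_size = voxel_size,
    bundles = list(bundle_spec("tube", cl, radius, qa = qa,
                               angular_jitter_sd = jitter_sd,
                               hemisphere = "L")),
    label_regions = list(
      list(name = "EndA", min_corner = c(4, y0 - 4, 4),
           max_corner = c(16, y0 + 4, 16)),
      list(name = "EndB", min_corner = c(4, y1 - 4, 4),
           max_corner = c(16, y1 + 4, 16))
    ),
    n_truth = n_truth, seed = seed
  )
}

#' @rdname phantom_configs
#' @export
asymmetric_tube_pair_config <- function(asymmetry = 1.17, length = 40,
                                        radius = 3, voxel_size = 1,
                                        jitter_sd = 0, qa = 0.5,
                                        n_truth = 10L, seed = 1L) {
  y0 <- 12; y1 <- y0 + length
  mk <- function(x, hem) bundle_spec(
    paste0("tube_", hem), rbind(c(x, y0, 10), c(x, y1, 10)), radius,
    qa = qa, angular_jitter_sd = jitter_sd, hemisphere = hem)
  lab <- function(nm, x, y) list(name = nm, min_corner = c(x - 6, y - 4, 4),
                                 max_corner = c(x + 6, y + 4, 16))
  phantom_config(
    grid_shape = c(40L, ceiling(y1 + radius + 6), 20L),
    voxel_size = voxel_size,
    bundles = list(mk(10, "L"), mk(30, "R")),
    label_regions = list(lab("LA", 10, y0), lab("LB", 10, y1),
                         lab("RA", 30, y0), lab("RB", 30, y1)),
    asymmetry = asymmetry, n_truth = n_truth, seed = seed
  )
}

#' @rdname phantom_configs
#' @export
crossing_phantom_config <- function(radius = 3, jitter_sd = 5, qa = 0.5,
                                    n_truth = 10L, seed = 1L) {
  tube1 <- bundle_spec("tube1", rbind(c(30, 10, 10), c(30, 50, 10)),
                       radius, qa = qa, angular_jitter_sd = jitter_sd,
                       hemisphere = "L")
  tube2 <- bundle_spec("tube2", rbind(c(10, 30, 10), c(50, 30, 10)),
                       radius, qa = qa, angular_jitter_sd = jitter_sd,
                       hemisphere = NA_character_)
  phantom_config(
    grid_shape = c(60L, 60L, 20L), voxel_size = 1,
    bundles = list(tube1),
    crossing_bundle = tube2,
    label_regions = list(
      list(name = "A1", min_corner = c(23, 5, 3), max_corner = c(37, 13, 17)),
      list(name = "B1", min_corner = c(23, 47, 3), max_corner = c(37, 55, 17)),
      list(name = "A2", min_corner = c(5, 23, 3), max_corner = c(13, 37, 17)),
      list(name = "B2", min_corner = c(47, 23, 3), max_corner = c(55, 37, 17))
    ),
    n_truth = n_truth, seed = seed
  )
}

#' @rdname phantom_configs
#' @export
ilf_phantom_config <- function(asymmetry = 1.17, jitter_sd = 0, radius = 3,
                               qa = 0.5, crossing = FALSE, n_truth = 10L,
                               seed = 1L) {
  mk_bundle <- function(hem) {
    m <- function(x) if (hem == "L") x else 56 - x     # mirror about x = 28
    cl <- rbind(c(m(14), 12, 20), c(m(13), 30, 15),
                c(m(14), 48, 16), c(m(15), 70, 20))
    fork <- centerline_point(cl, 0.75)
    dorsal <- rbind(fork, c(m(15), 70, 26), c(m(15), 78, 30))
    ventral <- rbind(fork, c(m(15), 70, 12), c(m(15), 78, 9))
    bundle_spec(paste0("ILF_", hem), cl, radius, qa = qa,
                angular_jitter_sd = jitter_sd, branch_point = 0.75,
                branches = list(dorsal = dorsal, ventral = ventral),
                hemisphere = hem)
  }
  labels <- list(
    list(name = "ATL_L", min_corner = c(6, 8, 8), max_corner = c(22, 16, 32)),
    list(name = "OCd_L", min_corner = c(6, 72, 22), max_corner = c(24, 84, 40)),
    list(name = "OCv_L", min_corner = c(6, 72, 2), max_corner = c(24, 84, 16)),
    list(name = "ATL_R", min_corner = c(34, 8, 8), max_corner = c(50, 16, 32)),
    list(name = "OCd_R", min_corner = c(32, 72, 22), max_corner = c(50, 84, 40)),
    list(name = "OCv_R", min_corner = c(32, 72, 2), max_corner = c(50, 84, 16))
  )
  cross <- NULL
  if (crossing) {
    cross <- bundle_spec("crossing",
                         rbind(c(4, 40, 15), c(24, 40, 15)), radius,
                         qa = qa, angular_jitter_sd = jitter_sd,
                         hemisphere = NA_character_)
    labels <- c(labels, list(
      list(name = "XA", min_corner = c(0, 34, 9), max_corner = c(7, 46, 21)),
      list(name = "XB", min_corner = c(21, 34, 9), max_corner = c(27, 46, 21))
    ))
  }
  phantom_config(
    grid_shape = c(56L, 90L, 50L), voxel_size = 1,
    bundles = list(mk_bundle("L"), mk_bundle("R")),
    label_regions = labels,
    asymmetry = asymmetry, crossing_bundle = cross,
    n_truth = n_truth, seed = seed
  )
}
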