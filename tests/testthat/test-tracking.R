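test_that("select_orientation picks the most congruent admissible peak", {
  p <- tracking_params()
  rot_y <- function(deg) c(sin(deg * pi / 180), cos(deg * pi / 180), 0)
  inc <- c(0, 1, 0)

  # 30 vs 80 degrees: only the 30-degree candidate is under the threshold
  got <- select_orientation(inc, rbind(rot_y(80), rot_y(30)), c(0.5, 0.5), p)
  expect_equal(got, rot_y(30), tolerance = 1e-12)

  # anti-parallel candidate: sign-flipped to align with the incoming axis
  got <- select_orientation(inc, rbind(-inc), 0.5, p)
  expect_equal(got, inc)

  # brute-force argmax over signed candidates
  cand <- rbind(rot_y(40), rot_y(10), rot_y(55))
  signed <- rbind(cand, -cand)
  oracle <- signed[which.max(signed %*% inc), ]
  expect_equal(select_orientation(inc, cand, rep(0.5, 3), p), oracle)
  expect_equal(oracle, rot_y(10))

  # QA gate: the best-aligned peak is skipped when below threshold
  got <- select_orientation(inc, rbind(rot_y(10), rot_y(40)), c(0.01, 0.5), p)
  expect_equal(got, rot_y(40), tolerance = 1e-12)
  # nothing admissible
  expect_null(select_orientation(inc, rbind(rot_y(75)), 0.5, p))
  expect_null(select_orientation(inc, rbind(rot_y(10)), 0.01, p))
  expect_null(select_orientation(inc, matrix(numeric(0), 0, 3), numeric(0), p))
})

test_that("step_direction blends 20/80 and never increases the turning angle", {
  p <- tracking_params()
  expect_equal(step_direction(c(0, 1, 0), c(0, 1, 0), p), c(0, 1, 0))
  # independent hand computation: normalize(0.2, 0.8, 0)
  got <- step_direction(c(1, 0, 0), c(0, 1, 0), p)
  expect_equal(got, c(0.2425356, 0.9701425, 0), tolerance = 1e-6)
  expect_equal(sqrt(sum(got^2)), 1)
  # degenerate weight: w_incoming = 0 returns the peak exactly
  p0 <- tracking_params(w_incoming = 0)
  expect_equal(step_direction(c(1, 0, 0), c(0, 1, 0), p0), c(0, 1, 0))
  # angle contraction property over random unit pairs under 60 degrees
  set.seed(42)
  for (i in 1:50) {
    inc <- rnorm(3); inc <- inc / sqrt(sum(inc^2))
    v <- rnorm(3); v <- v / sqrt(sum(v^2))
    if (sum(inc * v) < 0) v <- -v
    out <- step_direction(inc, v, p)
    expect_lte(acos(pmin(1, sum(out * inc))),
               acos(pmin(1, sum(v * inc))) + 1e-12)
  }
})

test_that("propagation through a straight tube matches straight-line integration", {
  ds <- fx_tube()
  p <- tracking_params()
  seed <- c(10.5, 32.5, 10.5)   # mid-tube voxel center
  sl <- propagate(ds$field, seed, p)
  expect_false(is.null(sl))

  # oracle: independent straight-line integration along +/- y from the seed,
  # stepping 0.2 mm until the containing voxel loses QA support
  supported <- function(pt) {
    i0 <- floor(pt)
    all(i0 >= 0) && all(i0 < ds$field$grid_shape) &&
      ds$field$qa[i0[1] + 1, i0[2] + 1, i0[3] + 1, 1] >= p$qa_threshold
  }
  n_steps <- function(dir) {
    pos <- seed; n <- 0
    repeat {
      pos <- pos + 0.2 * dir
      if (!supported(pos)) break
      n <- n + 1
    }
    n
  }
  expected_len <- (n_steps(c(0, 1, 0)) + n_steps(c(0, -1, 0))) * 0.2
  got_len <- (nrow(sl) - 1) * 0.2
  expect_lt(abs(got_len - expected_len), 2 * p$step_size + 1e-9)
  # covers the nominal 40 mm tube and ends inside the end labels
  expect_gte(got_len, 40 - 2 * p$step_size)
  expect_identical(assign_endpoint(sl[1, ], ds$atlas), "EndA")
  expect_identical(assign_endpoint(sl[nrow(sl), ], ds$atlas), "EndB")
})

test_that("propagation terminates on background, short tubes, and max_steps", {
  ds <- fx_tube()
  expect_null(propagate(ds$field, c(2.5, 2.5, 2.5)))      # QA = 0 voxel
  short <- generate_phantom(tube_phantom_config(length = 10, seed = 1L))
  expect_null(propagate(short$field, c(10.5, 17.5, 10.5)))  # < min_length
  # a permissive min_length recovers the short tube
  sl <- propagate(short$field, c(10.5, 17.5, 10.5),
                  tracking_params(min_length = 5))
  expect_false(is.null(sl))
  # max_steps bounds the point count even with huge limits elsewhere
  capped <- propagate(ds$field, c(10.5, 32.5, 10.5),
                      tracking_params(max_steps = 20L, min_length = 1))
  expect_lte(nrow(capped), 2 * 20 + 1)
})

test_that("accepted streamlines satisfy step, angle and length invariants", {
  b <- fx_tube_bundle()
  p <- tracking_params()
  expect_gt(length(b$streamlines), 0)
  for (sl in b$streamlines[seq(1, length(b$streamlines), by = 7)]) {
    steps <- sqrt(rowSums(diff(sl)^2))
    expect_true(all(abs(steps - p$step_size) < 1e-6))
    d <- diff(sl) / steps
    if (nrow(d) > 1) {
      cosang <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
      expect_true(all(acos(pmin(1, pmax(-1, cosang))) <
                        p$angle_threshold * pi / 180 + 1e-9))
    }
    expect_gte((nrow(sl) - 1) * p$step_size, p$min_length)
  }
})

test_that("track_bundle caps at max_streamlines and is deterministic", {
  ds <- fx_tube()
  seeds <- seeds_from_mask(ds$bundle_masks$tube, ds$field$voxel_size)
  p <- tracking_params(max_streamlines = 10L)
  b <- track_bundle(ds$field, seeds, p)
  expect_identical(length(b$streamlines), 10L)

  b1 <- track_bundle(ds$field, seeds[1:50, ], tracking_params())
  b2 <- track_bundle(ds$field, seeds[1:50, ], tracking_params())
  expect_identical(b1$streamlines, b2$streamlines)

  # empty seed region warns and yields an empty bundle
  expect_warning(b0 <- track_bundle(ds$field, matrix(c(2.5, 2.5, 2.5), 1)),
                 "no seed")
  expect_identical(length(b0$streamlines), 0L)
})

test_that("multi-peak propagation resolves crossings; averaging does not", {
  ds <- fx_crossing()
  seeds <- seeds_from_mask(ds$bundle_masks$tube1, ds$field$voxel_size,
                           every = 4L)
  rate <- function(field) {
    b <- track_bundle(field, seeds)
    cm <- count_matrix(b, ds$atlas)
    ok <- cm$counts$count[cm$counts$region_a == "A1" &
                          cm$counts$region_b == "B1"]
    (if (length(ok)) ok else 0L) / max(1L, cm$total_fibers)
  }
  expect_gte(rate(ds$field), 0.9)
  expect_lt(rate(degrade_to_single_peak(ds$field)), 0.5)
})
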