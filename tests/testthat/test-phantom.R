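test_that("phantom generation is deterministic and peaks are unit vectors", {
  cfg <- tube_phantom_config(jitter_sd = 3, seed = 11L)
  d1 <- generate_phantom(cfg)
  d2 <- generate_phantom(cfg)
  expect_identical(d1$field$peaks, d2$field$peaks)
  expect_identical(d1$field$qa, d2$field$qa)
  expect_identical(d1$truth_streamlines, d2$truth_streamlines)

  nrm <- sqrt(apply(d1$field$peaks^2, 1:4, sum))
  present <- d1$field$qa > 0
  expect_true(all(abs(nrm[present] - 1) < 1e-6))
  expect_true(all(d1$field$qa[!present] == 0))
})

test_that("noise-free peaks equal the exact local centerline tangent", {
  ds <- fx_tube()   # straight tube along +y, no jitter
  present <- which(ds$field$qa[, , , 1] > 0)
  idx <- arrayInd(present, ds$field$grid_shape)
  dirs <- cbind(ds$field$peaks[cbind(idx, 1L, 1L)],
                ds$field$peaks[cbind(idx, 1L, 2L)],
                ds$field$peaks[cbind(idx, 1L, 3L)])
  expect_true(all(abs(dirs[, 1]) < 1e-9))
  expect_true(all(abs(dirs[, 2] - 1) < 1e-9))
  expect_true(all(abs(dirs[, 3]) < 1e-9))
})

test_that("tube volume matches the analytic cylinder and a voxel-count oracle", {
  ds <- fx_tube()   # radius 2 mm, centerline length 40 mm, 1 mm voxels
  analytic_ml <- pi * 2^2 * 40 / 1000
  expect_lt(abs(ds$truth_volumes[["tube"]] - analytic_ml) / analytic_ml, 0.15)

  # independent oracle: count voxel centers within radius of the segment
  gs <- ds$field$grid_shape
  ctr <- voxel_center(arrayInd(seq_len(prod(gs)), gs) - 1L,
                      ds$field$voxel_size)
  y0 <- 12; y1 <- 52
  yc <- pmin(pmax(ctr[, 2], y0), y1)
  d2 <- (ctr[, 1] - 10)^2 + (ctr[, 2] - yc)^2 + (ctr[, 3] - 10)^2
  expect_equal(ds$truth_volumes[["tube"]], sum(d2 <= 4) / 1000)
})

test_that("crossing voxels carry two peaks at the crossing angle", {
  ds <- generate_phantom(crossing_phantom_config(jitter_sd = 0, seed = 1L))
  both <- ds$bundle_masks$tube1 & ds$bundle_masks$tube2
  expect_gt(sum(both), 0)
  expect_true(all(ds$field$n_peaks[both] == 2L))
  idx <- arrayInd(which(both), ds$field$grid_shape)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    v1 <- ds$field$peaks[i[1], i[2], i[3], 1, ]
    v2 <- ds$field$peaks[i[1], i[2], i[3], 2, ]
    expect_lt(abs(sum(v1 * v2)), 1e-9)   # 90 degrees exactly, no jitter
  }
  # single-tube voxels carry exactly one peak
  only1 <- ds$bundle_masks$tube1 & !ds$bundle_masks$tube2
  expect_true(all(ds$field$n_peaks[only1] == 1L))
})

test_that("jittered crossing keeps the pairwise angle near 90 degrees", {
  ds <- fx_crossing()   # 5 degree jitter
  both <- ds$bundle_masks$tube1 & ds$bundle_masks$tube2
  idx <- arrayInd(which(both), ds$field$grid_shape)
  ang <- vapply(seq_len(nrow(idx)), function(r) {
    i <- idx[r, ]
    v1 <- ds$field$peaks[i[1], i[2], i[3], 1, ]
    v2 <- ds$field$peaks[i[1], i[2], i[3], 2, ]
    acos(pmin(1, abs(sum(v1 * v2)))) * 180 / pi
  }, numeric(1))
  expect_true(all(abs(ang - 90) < 30))
  # acos(|dot|) folds at 90 degrees, biasing the mean low by roughly the
  # mean absolute angular perturbation (~4 degrees for two 5-degree jitters)
  expect_lt(abs(mean(ang) - 90), 8)
  expect_gt(mean(ang), 80)
})

test_that("hemispheric volume ratio tracks asymmetry squared", {
  for (a in c(1, 1.17, 1.4)) {
    ds <- generate_phantom(ilf_phantom_config(asymmetry = a, jitter_sd = 0,
                                              seed = 3L))
    ratio <- ds$truth_volumes[["ILF_L"]] / ds$truth_volumes[["ILF_R"]]
    expect_lt(abs(ratio - a^2) / a^2, 0.2)
  }
})

test_that("symmetric configurations have identical hemispheric volumes", {
  ds <- generate_phantom(ilf_phantom_config(asymmetry = 1, jitter_sd = 0,
                                            seed = 5L))
  expect_equal(ds$truth_volumes[["ILF_L"]], ds$truth_volumes[["ILF_R"]])
  expect_equal(laterality_index(ds$truth_volumes[["ILF_L"]],
                                ds$truth_volumes[["ILF_R"]]), 0)
})

test_that("ground-truth connectivity counts each truth streamline once", {
  ds <- fx_tube()
  tc <- ds$truth_connectivity
  expect_identical(nrow(tc), 1L)
  expect_identical(tc$count, 10L)           # n_truth per path
  expect_setequal(c(tc$region_a, tc$region_b), c("EndA", "EndB"))

  # bifurcated bundle: n per branch into each posterior label
  ilf <- fx_ilf()
  tcl <- ilf$truth_connectivity[ilf$truth_connectivity$bundle == "ILF_L", ]
  expect_setequal(tcl$region_b, c("OCd_L", "OCv_L"))
  expect_true(all(tcl$region_a == "ATL_L"))
  expect_true(all(tcl$count == ilf$config$n_truth))
})

test_that("endpoints slightly outside a label are still assigned to it", {
  ds <- fx_tube()
  # brute-force nearest-label oracle at a point one voxel beyond EndA
  p <- c(10.5, 7.5, 10.5)    # EndA spans y in [8, 16]
  gs <- dim(ds$atlas$volume)
  i0 <- voxel_of(p, ds$atlas$voxel_size)
  best <- Inf; best_lab <- 0L
  for (dx in -2:2) for (dy in -2:2) for (dz in -2:2) {
    j <- i0 + c(dx, dy, dz)
    if (any(j < 0) || any(j >= gs)) next
    lab <- ds$atlas$volume[j[1] + 1, j[2] + 1, j[3] + 1]
    d <- sqrt(sum((j - i0)^2))
    if (lab > 0 && d <= 2 && d < best) { best <- d; best_lab <- lab }
  }
  expect_identical(assign_endpoint(p, ds$atlas, radius = 2),
                   ds$atlas$names[best_lab])
  expect_identical(assign_endpoint(p, ds$atlas, radius = 2), "EndA")
})

test_that("invalid configurations are rejected", {
  # bundle leaving the grid
  cfg <- phantom_config(
    grid_shape = c(10, 10, 10), voxel_size = 1,
    bundles = list(bundle_spec("b", rbind(c(5, 1, 5), c(5, 30, 5)), 2)),
    label_regions = list(list(name = "A", min_corner = c(0, 0, 0),
                              max_corner = c(3, 3, 3))))
  expect_error(generate_phantom(cfg), "outside the grid")

  # overlapping label regions
  cfg2 <- tube_phantom_config()
  cfg2$label_regions[[2]] <- list(name = "B", min_corner = c(4, 10, 4),
                                  max_corner = c(16, 20, 16))
  expect_error(generate_phantom(cfg2), "overlap")

  # branch centerlines must share the fork point
  cl <- rbind(c(5, 1, 5), c(5, 9, 5))
  expect_error(
    bundle_spec("b", cl, 1, branch_point = 0.5,
                branches = list(rbind(c(9, 9, 9), c(9, 9, 10)),
                                rbind(c(5, 5, 5), c(1, 1, 1)))),
    "fork")
})
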