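make_test_atlas <- function() {
  vol <- array(0L, c(10, 10, 10))
  vol[1:3, 1:3, 1:3] <- 1L
  vol[7:9, 7:9, 7:9] <- 2L
  vol[1:3, 7:9, 1:3] <- 3L
  region_atlas(vol, c("A", "B", "C"), 1)
}

test_that("endpoint assignment: direct, nearest-within-radius, unassigned", {
  at <- make_test_atlas()
  expect_identical(assign_endpoint(c(1.5, 1.5, 1.5), at), "A")
  expect_identical(assign_endpoint(c(8, 8, 8), at), "B")
  # background 1 voxel from region A: exhaustive neighborhood oracle
  p <- c(3.5, 1.5, 1.5)
  expect_identical(assign_endpoint(p, at, radius = 2), "A")
  expect_identical(assign_endpoint(p, at, radius = 0), "unassigned")
  # far background and out-of-grid
  expect_identical(assign_endpoint(c(0.5, 5.5, 9.5), at, 2), "unassigned")
  expect_identical(assign_endpoint(c(-1, 5, 5), at, 2), "unassigned")
  # tie at equal distance: lowest label wins (midway between A and C)
  vol <- array(0L, c(5, 5, 5))
  vol[1, 1, 1] <- 2L
  vol[3, 1, 1] <- 1L
  at2 <- region_atlas(vol, c("P", "Q"), 1)
  expect_identical(assign_endpoint(c(1.5, 0.5, 0.5), at2, 2), "P")
})

test_that("count_matrix counts unordered pairs and conserves totals", {
  at <- make_test_atlas()
  a2b <- lapply(1:50, function(i) rbind(c(1.5, 1.5, 1.5), c(8, 8, 8)))
  b2a <- lapply(1:20, function(i) rbind(c(8, 8, 8), c(1.5, 1.5, 1.5)))
  a2c <- lapply(1:30, function(i) rbind(c(1.5, 1.5, 1.5), c(1.5, 8, 1.5)))
  self_ <- list(rbind(c(1.5, 1.5, 1.5), c(2.5, 2.5, 2.5)))
  lost <- list(rbind(c(1.5, 1.5, 1.5), c(0.5, 5.5, 9.5)))
  cm <- count_matrix(bundle(c(a2b, b2a, a2c, self_, lost)), at)

  expect_identical(cm$total_fibers, 102L)
  expect_identical(cm$unassigned, 1L)
  get <- function(a, b) cm$counts$count[cm$counts$region_a == a &
                                        cm$counts$region_b == b]
  expect_identical(get("A", "B"), 70L)   # direction-agnostic
  expect_identical(get("A", "C"), 30L)
  expect_identical(get("A", "A"), 1L)    # self-pair retained
  expect_identical(sum(cm$counts$count) + cm$unassigned, cm$total_fibers)
})

test_that("normalization divides by total fibers and rejects empty bundles", {
  at <- make_test_atlas()
  sls <- c(lapply(1:30, function(i) rbind(c(1.5, 1.5, 1.5), c(8, 8, 8))),
           lapply(1:70, function(i) rbind(c(1.5, 1.5, 1.5), c(1.5, 8, 1.5))))
  pr <- normalize_counts(count_matrix(bundle(sls), at))
  expect_equal(sort(pr$proportion), c(0.3, 0.7))
  expect_true(all(pr$proportion >= 0 & pr$proportion <= 1))
  cm0 <- count_matrix(bundle(list(rbind(c(1.5, 1.5, 1.5), c(8, 8, 8)))), at)
  cm0$total_fibers <- 0L
  expect_error(normalize_counts(cm0), "total_fibers")
})

test_that("CI scaling: mean across subjects, global max to 100", {
  regions <- c("A", "B", "C")
  subj <- function(pp, pq) make_props(c("A", "A"), c("B", "C"),
                                      c(pp, pq), regions)
  ci <- scale_ci(list(subj(0.2, 0.1), subj(0.4, 0.1), subj(0.6, 0.1)))
  expect_equal(ci$ci[ci$region_b == "B"], 100)   # mean 0.4 -> max
  expect_equal(ci$ci[ci$region_b == "C"], 25)    # mean 0.1 -> 25

  # one subject, one connection: CI = 100
  one <- scale_ci(list(make_props("A", "B", 0.37, regions)))
  expect_equal(one$ci, 100)

  # a pair absent in every subject has CI 0
  with_zero <- scale_ci(list(make_props(c("A", "B"), c("B", "C"),
                                        c(0.5, 0), regions)))
  expect_equal(with_zero$ci[with_zero$region_a == "B"], 0)

  # subject permutation invariance
  s <- list(subj(0.2, 0.1), subj(0.4, 0.1), subj(0.6, 0.1))
  ci_perm <- scale_ci(s[c(3, 1, 2)])
  expect_equal(ci_perm[order(ci_perm$region_b), "ci"],
               ci[order(ci$region_b), "ci"])

  # inconsistent region universes are rejected
  expect_error(scale_ci(list(subj(0.2, 0.1),
                             make_props("A", "B", 0.5, c("A", "B")))),
               "inconsistent")
})

test_that("CI is invariant under uniform count scaling and maxes at 100", {
  at <- make_test_atlas()
  mk <- function(mult) {
    sls <- c(lapply(seq_len(3 * mult),
                    function(i) rbind(c(1.5, 1.5, 1.5), c(8, 8, 8))),
             lapply(seq_len(7 * mult),
                    function(i) rbind(c(1.5, 1.5, 1.5), c(1.5, 8, 1.5))))
    normalize_counts(count_matrix(bundle(sls), at))
  }
  ci1 <- scale_ci(list(mk(1)))
  ci5 <- scale_ci(list(mk(5)))
  expect_equal(ci1$ci, ci5$ci)
  expect_equal(max(ci1$ci), 100)
})

test_that("connectogram export writes karyotype, links and a CSV round trip", {
  regions <- c("A", "B", "C")
  ci <- scale_ci(list(make_props(c("A", "A", "B", "A"),
                                 c("B", "C", "C", "A"),
                                 c(0.5, 0.2, 0.1, 0.3), regions)))
  dir <- withr::local_tempdir()
  paths <- export_connectogram(ci, dir, prefix = "test")
  expect_identical(length(readLines(paths$karyotype)), 3L)
  # self-pair (A,A) excluded from links; 3 nonzero inter-region pairs
  expect_identical(length(readLines(paths$links)), 3L)
  back <- utils::read.csv(paths$csv)
  expect_equal(back$ci, ci$ci)
  expect_identical(back$region_a, ci$region_a)

  # empty CI: valid karyotype, no links
  empty <- scale_ci(list(make_props(character(0), character(0),
                                    numeric(0), regions)))
  p2 <- export_connectogram(empty, dir, prefix = "empty")
  expect_identical(length(readLines(p2$links)), 0L)
  expect_identical(length(readLines(p2$karyotype)), 3L)
})

test_that("tracked counts recover the phantom ground-truth table exactly", {
  ds <- fx_tube()
  b <- fx_tube_bundle()
  cm <- count_matrix(b, ds$atlas)
  truth <- ds$truth_connectivity
  expect_identical(paste(cm$counts$region_a, cm$counts$region_b),
                   paste(truth$region_a, truth$region_b))
  expect_identical(cm$unassigned, 0L)
  expect_identical(sum(cm$counts$count), cm$total_fibers)
})
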