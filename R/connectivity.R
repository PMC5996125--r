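#' Region atlas
#'
#' An integer label volume naming termination regions. Label 0 is
#' background; every nonzero label must be named.
#'
#' @param volume integer 3-D array of labels.
#' @param names character vector; `names[i]` is the name of label `i`.
#' @param voxel_size mm per axis.
#' @return An object of class `region_atlas`.
#' @export
region_atlas <- function(volume, names, voxel_size) {
  storage.mode(volume) <- "integer"
  labs <- sort(unique(volume[volume > 0L]))
  if (length(labs) && max(labs) > length(names))
    stop("every nonzero label needs a name")
  structure(
    list(volume = volume, names = as.character(names),
         voxel_size = rep_len(as.numeric(voxel_size), 3L)),
    class = "region_atlas"
  )
}

#' Assign a streamline endpoint to an atlas region
#'
#' Returns the name of the endpoint voxel's label. If that voxel is
#' background, the nearest nonzero label within `radius` voxels (Euclidean
#' distance between voxel indices; nearest wins, lowest label on ties) is
#' used — streamlines terminate at anisotropy boundaries slightly short of
#' the labeled regions. Otherwise, or when the endpoint lies outside the
#' grid, `"unassigned"`.
#'
#' @param endpoint length-3 mm position.
#' @param atlas a [region_atlas()].
#' @param radius search radius in voxels (default 2).
#' @return Region name, or `"unassigned"`.
#' @export
assign_endpoint <- function(endpoint, atlas, radius = 2) {
  gs <- dim(atlas$volume)
  i0 <- voxel_of(endpoint, atlas$voxel_size)
  if (any(i0 < 0L) || any(i0 >= gs)) return("unassigned")
  lab <- atlas$volume[i0[1] + 1L, i0[2] + 1L, i0[3] + 1L]
  if (lab > 0L) return(atlas$names[lab])
  if (radius <= 0) return("unassigned")
  r <- ceiling(radius)
  off <- as.matrix(expand.grid(-r:r, -r:r, -r:r))
  d2 <- rowSums(off^2)
  ord <- order(d2)
  off <- off[ord, , drop = FALSE]
  d2 <- d2[ord]
  keep <- d2 <= radius^2
  off <- off[keep, , drop = FALSE]
  d2 <- d2[keep]
  cand <- sweep(off, 2L, i0, "+")
  ok <- cand[, 1] >= 0L & cand[, 1] < gs[1] &
        cand[, 2] >= 0L & cand[, 2] < gs[2] &
        cand[, 3] >= 0L & cand[, 3] < gs[3]
  cand <- cand[ok, , drop = FALSE]
  d2 <- d2[ok]
  labs <- atlas$volume[cand + 1L]
  hit <- which(labs > 0L)
  if (length(hit) == 0L) return("unassigned")
  best_d2 <- d2[hit[1L]]
  at_best <- hit[d2[hit] == best_d2]
  atlas$names[min(labs[at_best])]
}

#' Streamline-termination count matrix
#'
#' Assigns both endpoints of every streamline to atlas regions and counts
#' each streamline once under its unordered region pair (self-pairs, both
#' endpoints in the same region, are retained). Streamlines with at least
#' one unassigned endpoint increment `unassigned` and contribute to no
#' pair, so `sum(counts) + unassigned = total_fibers` always holds.
#'
#' @param bundle a [bundle()].
#' @param atlas a [region_atlas()].
#' @param radius endpoint assignment radius in voxels.
#' @return An object of class `count_matrix`: list with `counts` (data
#'   frame `region_a`, `region_b`, `count`; `region_a <= region_b`),
#'   `total_fibers`, `unassigned`, `regions` (the atlas region universe),
#'   `subject`, `fascicle`.
#' @export
count_matrix <- function(bundle, atlas, radius = 2) {
  stopifnot(inherits(bundle, "bundle"), inherits(atlas, "region_atlas"))
  pairs <- vapply(bundle$streamlines, function(p) {
    a <- assign_endpoint(p[1L, ], atlas, radius)
    b <- assign_endpoint(p[nrow(p), ], atlas, radius)
    if (a == "unassigned" || b == "unassigned") return(NA_character_)
    paste(sort(c(a, b)), collapse = "\r")
  }, character(1))
  unassigned <- sum(is.na(pairs))
  tab <- table(pairs[!is.na(pairs)])
  counts <- if (length(tab)) {
    pr <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    data.frame(region_a = pr[, 1L], region_b = pr[, 2L],
               count = as.integer(tab), row.names = NULL)
  } else {
    data.frame(region_a = character(0), region_b = character(0),
               count = integer(0))
  }
  structure(
    list(counts = counts, total_fibers = length(bundle$streamlines),
         unassigned = unassigned, regions = atlas$names,
         subject = bundle$provenance$subject,
         fascicle = bundle$provenance$fascicle),
    class = "count_matrix"
  )
}

#' Normalize a count matrix to per-fascicle proportions
#'
#' Each region-pair count is divided by the fascicle's total number of
#' fibers (not by the number of assigned fibers), so proportions are
#' comparable across subjects regardless of unassigned endpoints.
#'
#' @param matrix a [count_matrix()].
#' @return Data frame `region_a`, `region_b`, `proportion` (in `[0, 1]`),
#'   with the region universe attached as attribute `regions`.
#' @export
normalize_counts <- function(matrix) {
  stopifnot(inherits(matrix, "count_matrix"))
  if (matrix$total_fibers == 0L)
    stop("cannot normalize a count matrix with total_fibers = 0")
  out <- data.frame(region_a = matrix$counts$region_a,
                    region_b = matrix$counts$region_b,
                    proportion = matrix$counts$count / matrix$total_fibers)
  attr(out, "regions") <- matrix$regions
  out
}

#' Scale per-subject connection proportions to a 0-100 connection index
#'
#' Per region pair, the mean proportion across subjects is taken; the
#' resulting table is divided by its maximum and multiplied by 100, giving
#' a connection index (CI) between 0 and 100 — 0 for no connectivity, 100
#' for the strongest relative connection. An all-zero table stays all-zero.
#'
#' @param proportions list over subjects of [normalize_counts()] outputs;
#'   all subjects must share one region universe.
#' @param fascicle fascicle tag recorded in the result.
#' @return An object of class `ci_table`: data frame `region_a`,
#'   `region_b`, `ci` covering every pair nonzero in any subject, with
#'   attributes `regions` and `fascicle`.
#' @export
scale_ci <- function(proportions, fascicle = "whole") {
  stopifnot(length(proportions) >= 1L)
  unis <- lapply(proportions, attr, "regions")
  for (u in unis) if (!identical(sort(u), sort(unis[[1L]])))
    stop("subjects have inconsistent region universes")
  key <- lapply(proportions, function(p) paste(p$region_a, p$region_b,
                                               sep = "\r"))
  all_keys <- sort(unique(unlist(key)))
  acc <- matrix(0, length(all_keys), length(proportions),
                dimnames = list(all_keys, NULL))
  for (s in seq_along(proportions))
    acc[key[[s]], s] <- proportions[[s]]$proportion
  m <- rowMeans(acc)
  mx <- if (length(m)) max(m) else 0
  ci <- if (mx > 0) m / mx * 100 else m
  pr <- if (length(all_keys))
    do.call(rbind, strsplit(all_keys, "\r", fixed = TRUE))
  else matrix(character(0), 0L, 2L)
  out <- data.frame(region_a = pr[, 1L], region_b = pr[, 2L], ci = ci,
                    row.names = NULL)
  attr(out, "regions") <- unis[[1L]]
  attr(out, "fascicle") <- fascicle
  class(out) <- c("ci_table", class(out))
  out
}

#' Export a connection-index table as CIRCOS-ready text
#'
#' Writes three plain-text files: a CIRCOS karyotype (one band per region
#' of the universe, unit length), a links file (one line per nonzero
#' inter-region pair, link weight = CI; self-pairs are excluded), and a
#' tidy CSV of the full table.
#'
#' @param ci a `ci_table` from [scale_ci()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths of `karyotype`, `links` and `csv`.
#' @export
export_connectogram <- function(ci, dir, prefix = "connectogram") {
  stopifnot(inherits(ci, "ci_table"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  regions <- attr(ci, "regions")
  kpath <- file.path(dir, paste0(prefix, "_karyotype.txt"))
  lpath <- file.path(dir, paste0(prefix, "_links.txt"))
  cpath <- file.path(dir, paste0(prefix, "_ci.csv"))
  writeLines(sprintf("chr - %s %s 0 1 grey", regions, regions), kpath)
  nz <- ci$ci > 0 & ci$region_a != ci$region_b
  writeLines(sprintf("%s 0 1 %s 0 1 score=%.6g",
                     ci$region_a[nz], ci$region_b[nz], ci$ci[nz]), lpath)
  utils::write.csv(as.data.frame(ci), cpath, row.names = FALSE)
  invisible(list(karyotype = kpath, links = lpath, csv = cpath))
}
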