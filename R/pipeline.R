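#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis: the multi-subject
#' phantom (per-subject angular jitter emulates inter-subject variability;
#' `asymmetry` sets the simulated left:right radius ratio), the tracker,
#' the selection geometry (anterior sphere ROI + posterior coronal box ROI
#' per hemisphere, midline plane of avoidance), the posterior subdivision
#' plane, and the connectivity options.
#'
#' @param n_subjects number of simulated subjects.
#' @param asymmetry left:right bundle radius ratio of the phantom.
#' @param jitter_sd per-subject angular noise SD in degrees.
#' @param crossing include the orthogonal crossing bundle.
#' @param tracking a [tracking_params()].
#' @param seed_every seed every n-th bundle voxel (tracking density).
#' @param assignment_radius endpoint-to-label assignment radius in voxels.
#' @param seed master RNG seed; subject s uses `seed * 1000 + s`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 3L, asymmetry = 1.17,
                            jitter_sd = 5, crossing = FALSE,
                            tracking = tracking_params(),
                            seed_every = 3L, assignment_radius = 2,
                            seed = 1L) {
  structure(
    list(n_subjects = as.integer(n_subjects), asymmetry = asymmetry,
         jitter_sd = jitter_sd, crossing = crossing, tracking = tracking,
         seed_every = as.integer(seed_every),
         assignment_radius = assignment_radius, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Unknown keys are rejected; missing keys take the [pipeline_config()]
#' defaults. Tracking parameters nest under `tracking`.
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required for YAML configs")
      yaml::read_yaml(path)
    },
    stop("unsupported config format '.", ext, "'")
  )
  tk <- do.call(tracking_params, as.list(raw$tracking))
  raw$tracking <- NULL
  known <- setdiff(names(formals(pipeline_config)), "tracking")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, c(raw, list(tracking = tk)))
}

# Selection geometry matching the standard two-hemisphere phantom: an
# anterior temporal sphere, a posterior coronal box at the
# "temporo-occipital junction" (just beyond the fork), and a sagittal
# midline plane of avoidance.
ilf_selection_geometry <- function(hemisphere) {
  m <- function(x) if (hemisphere == "L") x else 56 - x
  list(
    include = list(
      sphere_roi(c(m(14), 12, 20), 8, name = paste0("ATL_sphere_",
                                                    hemisphere)),
      box_roi(c(min(m(2), m(27)), 58, 0), c(max(m(2), m(27)), 66, 50),
              name = paste0("TO_box_", hemisphere))
    ),
    exclude = list(plane_roa(1L, 28, thickness = 2, name = "midline"))
  )
}

#' Run the full analysis pipeline
#'
#' For each simulated subject: generate the two-hemisphere phantom (subject-
#' specific angular jitter), track each hemisphere from its bundle mask,
#' apply the two-ROI selection with midline exclusion, split the selected
#' bundle into dorsal and ventral sub-fascicles at the posterior plane, and
#' accumulate per-fascicle hemisphere-merged termination-count matrices and
#' per-hemisphere volumes. Across subjects, proportions are scaled to
#' 0-100 connection indices per fascicle; volumes yield lateralization
#' indices and Welch t-tests. All tabular outputs (CSV/JSON) and
#' CIRCOS-ready connectogram text files are written under `out_dir`,
#' together with the exact configuration, master seed and a config
#' checksum; a rerun with the same configuration is bit-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created).
#' @return Invisibly, a list with `ci` (per fascicle), `volumes` (data
#'   frame), `li` (data frame), `tests` (per fascicle Welch results) and
#'   `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fascicles <- c("whole", "dorsal", "ventral")
  props <- stats::setNames(vector("list", 3L), fascicles)
  vols <- list()
  post_plane <- plane_roa(2L, 62, name = "posterior")

  for (s in seq_len(config$n_subjects)) {
    ds <- generate_phantom(ilf_phantom_config(
      asymmetry = config$asymmetry, jitter_sd = config$jitter_sd,
      crossing = config$crossing, seed = config$seed * 1000L + s))
    vs <- ds$field$voxel_size
    per_hem <- list()
    for (hem in c("L", "R")) {
      seeds <- seeds_from_mask(ds$bundle_masks[[paste0("ILF_", hem)]],
                               vs, every = config$seed_every)
      b <- track_bundle(ds$field, seeds, config$tracking,
                        name = paste0("ILF_", hem),
                        subject = sprintf("sub%02d", s), hemisphere = hem)
      geo <- ilf_selection_geometry(hem)
      sel <- select_streamlines(b, geo$include, geo$exclude)
      if (length(sel$streamlines) == 0L) {
        warning("subject ", s, " hemisphere ", hem,
                ": empty selection; downstream stages skipped")
        next
      }
      sd_ <- split_dorsal_ventral(sel, post_plane, side = 1,
                                  voxel_size = vs)
      per_hem[[hem]] <- list(whole = sel, dorsal = sd_$dorsal,
                             ventral = sd_$ventral)
      for (f in fascicles) {
        bb <- per_hem[[hem]][[f]]
        vr <- bundle_volume(bb, vs, ds$field$grid_shape)
        vols[[length(vols) + 1L]] <- data.frame(
          subject = sprintf("sub%02d", s), hemisphere = hem, fascicle = f,
          n_streamlines = length(bb$streamlines),
          voxel_count = vr$voxel_count, volume_ml = vr$volume_ml)
      }
      if (s == 1L) {
        write_streamlines(sel, file.path(out_dir,
                                         sprintf("sub01_ILF_%s.tck", hem)))
      }
    }
    if (length(per_hem) < 2L) next
    for (f in fascicles) {
      merged <- bundle(c(per_hem$L[[f]]$streamlines,
                         per_hem$R[[f]]$streamlines),
                       name = paste0("ILF_", f),
                       subject = sprintf("sub%02d", s),
                       hemisphere = "LR", fascicle = f)
      cm <- count_matrix(merged, ds$atlas, config$assignment_radius)
      props[[f]][[s]] <- normalize_counts(cm)
    }
    if (s == 1L) {
      write_field_nifti(ds$field, file.path(out_dir, "sub01"))
      write_atlas_nifti(ds$atlas, file.path(out_dir, "sub01"))
    }
  }

  volumes <- do.call(rbind, vols)
  utils::write.csv(volumes, file.path(out_dir, "volumes.csv"),
                   row.names = FALSE)

  ci <- list(); tests <- list(); li_rows <- list()
  for (f in fascicles) {
    pf <- Filter(Negate(is.null), props[[f]])
    if (length(pf)) {
      ci[[f]] <- scale_ci(pf, fascicle = f)
      export_connectogram(ci[[f]], out_dir, prefix = paste0("ci_", f))
    }
    vL <- volumes$volume_ml[volumes$fascicle == f &
                            volumes$hemisphere == "L"]
    vR <- volumes$volume_ml[volumes$fascicle == f &
                            volumes$hemisphere == "R"]
    subL <- volumes$subject[volumes$fascicle == f &
                            volumes$hemisphere == "L"]
    both <- intersect(subL, volumes$subject[volumes$fascicle == f &
                                            volumes$hemisphere == "R"])
    for (sb in both) {
      l <- volumes$volume_ml[volumes$subject == sb & volumes$fascicle == f &
                             volumes$hemisphere == "L"]
      r <- volumes$volume_ml[volumes$subject == sb & volumes$fascicle == f &
                             volumes$hemisphere == "R"]
      li_rows[[length(li_rows) + 1L]] <- data.frame(
        subject = sb, fascicle = f, li = laterality_index(l, r))
    }
    if (length(vL) >= 2L && length(vR) >= 2L &&
        (stats::var(vL) + stats::var(vR)) > 0)
      tests[[f]] <- welch_t(vL, vR, tails = 2L)
  }
  li <- do.call(rbind, li_rows)
  utils::write.csv(li, file.path(out_dir, "lateralization.csv"),
                   row.names = FALSE)

  report <- list(
    n_subjects = config$n_subjects,
    mean_volume_ml = lapply(split(volumes$volume_ml,
                                  paste(volumes$fascicle,
                                        volumes$hemisphere, sep = "_")),
                            mean),
    mean_li = lapply(split(li$li, li$fascicle), mean),
    volume_welch = lapply(tests, function(w)
      list(t = w$t, df = w$df, p = w$p)),
    mean_ci = lapply(ci, function(tab) mean(tab$ci))
  )
  jsonlite::write_json(report, file.path(out_dir, "quant_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cfg <- unclass(config)
  cfg$tracking <- unclass(cfg$tracking)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  prov <- list(seed = config$seed,
               config_md5 = unname(tools::md5sum(cfg_path)),
               stages = c("phantom", "track", "select", "subdivide",
                          "connect", "quantify"),
               files = sort(list.files(out_dir)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ci = ci, volumes = volumes, li = li, tests = tests,
                 out_dir = out_dir))
}
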