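#' Stimulus presentation geometry
#'
#' Physical size of the on-screen stimulus area given its pixel dimensions
#' and the display's inter-pixel distance.
#'
#' @param width_px,height_px Stimulus area in pixels (defaults 960 x 540).
#' @param inter_pixel_mm Display inter-pixel distance in mm (default 0.16).
#' @return Named numeric `c(width_mm, height_mm)`.
#' @examples
#' stimulus_area_mm()  # 153.6 x 86.4 mm
#' @export
stimulus_area_mm <- function(width_px = 960, height_px = 540,
                             inter_pixel_mm = 0.16) {
  c(width_mm = width_px * inter_pixel_mm,
    height_mm = height_px * inter_pixel_mm)
}

#' Factorial group tables of the three experiments
#'
#' Returns the stimulus specification for every group of the requested
#' experiment: experiment 1 compares the fully natural moving fish against
#' four static variants and a blank control; experiment 2 manipulates two
#' features at a time; experiment 3 manipulates exactly one feature.
#'
#' @param experiment 1, 2 or 3.
#' @return Named list of [stimulus_spec()] objects (`NULL` for the Blank
#'   control).
#' @export
experiment_groups <- function(experiment) {
  spec <- stimulus_spec
  switch(as.character(experiment),
    "1" = list(
      "Normal" = spec(),
      "Static" = spec(locomotion = FALSE, body_motion = FALSE, static = TRUE),
      "Grey scale/Static" = spec(colour = "grey", locomotion = FALSE,
                                 body_motion = FALSE, static = TRUE),
      "Pressed/Static" = spec(shape = "pressed", locomotion = FALSE,
                              body_motion = FALSE, static = TRUE),
      "Pressed/Grey scale/Static" = spec(colour = "grey", shape = "pressed",
                                         locomotion = FALSE,
                                         body_motion = FALSE, static = TRUE),
      "Blank" = NULL),
    "2" = list(
      "Normal" = spec(),
      "Grey scale/No locomotion" = spec(colour = "grey", locomotion = FALSE),
      "Grey scale/No body motion" = spec(colour = "grey", body_motion = FALSE),
      "Pressed/Grey scale" = spec(colour = "grey", shape = "pressed"),
      "Pressed/No locomotion" = spec(shape = "pressed", locomotion = FALSE),
      "Pressed/No body motion" = spec(shape = "pressed", body_motion = FALSE)),
    "3" = list(
      "Normal" = spec(),
      "Pressed" = spec(shape = "pressed"),
      "Grey scale" = spec(colour = "grey"),
      "No locomotion" = spec(locomotion = FALSE),
      "No body motion" = spec(body_motion = FALSE)),
    stop("experiment must be 1, 2 or 3"))
}

#' Group x minute-bin hazard matrices with a planted attraction pattern
#'
#' Builds the entry-rate matrix for [assay_params()]: all groups share the
#' baseline entry hazard in bin 1; from stimulus onset the `Normal` group's
#' entry hazard rises to `normal_entry`, other stimulus groups to
#' `other_entry`, and any `Blank` group stays at baseline.
#'
#' @param groups Character vector of group labels (matched by name for
#'   `"Normal"` and `"Blank"`).
#' @param n_bins Total minute bins including baseline (default 6).
#' @param base_entry Baseline entry hazard, per second (default 0.02).
#' @param normal_entry Stimulus-period entry hazard of the Normal group.
#' @param other_entry Stimulus-period entry hazard of other stimulus groups.
#' @return `groups x n_bins` entry-rate matrix.
#' @export
make_demo_rates <- function(groups, n_bins = 6, base_entry = 0.02,
                            normal_entry = 0.12, other_entry = 0.05) {
  m <- matrix(base_entry, length(groups), n_bins,
              dimnames = list(groups, NULL))
  stim <- 2:n_bins
  for (g in groups) {
    m[g, stim] <- if (g == "Normal") normal_entry
      else if (g == "Blank") base_entry else other_entry
  }
  m
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end demo in one validated object.
#' Defaults reproduce the standard assay: 1-min baseline + 5-min stimulus at
#' 30 fps, 10-mm zone, 55-s baseline exclusion threshold, alpha 0.05, 1-min
#' swimmer recordings at 60 fps looped five times.
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @param experiment Which factorial design to materialise (1, 2 or 3).
#' @param n_per_group Subjects per group (defaults: 18 for experiment 1, 24
#'   otherwise).
#' @param swimmer Named list of overrides for [swimmer_params()].
#' @param entry_rates Optional explicit entry-rate matrix (see
#'   [make_demo_rates()]); built automatically when `NULL`.
#' @param exit_rate Zone exit hazard per second (default 0.10).
#' @param zone_mm,threshold_s Scoring parameters (defaults 10 mm, 55 s).
#' @param alpha Significance level (default 0.05).
#' @param repeats Loop count for stimulus animations (default 5).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, experiment = 1,
                            n_per_group = NULL, swimmer = list(),
                            entry_rates = NULL, exit_rate = 0.10,
                            zone_mm = 10, threshold_s = 55, alpha = 0.05,
                            repeats = 5) {
  groups <- names(experiment_groups(experiment))
  if (is.null(n_per_group)) n_per_group <- if (experiment == 1) 18L else 24L
  cfg <- list(seed = as.integer(seed), experiment = experiment,
              groups = groups, n_per_group = as.integer(n_per_group),
              swimmer = swimmer, entry_rates = entry_rates,
              exit_rate = exit_rate, zone_mm = zone_mm,
              threshold_s = threshold_s, alpha = alpha, repeats = repeats)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0)
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$entry_rates)) raw$entry_rates <- as.matrix(raw$entry_rates)
  do.call(pipeline_config, raw)
}

#' Full statistical analysis of a long-format score table
#'
#' Runs the analysis chain on group x time scores: multisample sphericity
#' test, split-plot ANOVA (Huynh-Feldt corrected when sphericity is rejected
#' at `alpha`), simple main effects when the interaction is significant, and
#' Ryan post-hoc comparisons of the group means (on the between-subjects
#' error) and of the time means (on the within error).
#'
#' @param long Long-format data as for [mixed_anova()].
#' @param alpha Significance level (default 0.05).
#' @return List with elements `sphericity`, `anova` (corrected when
#'   applicable), `anova_raw`, `posthoc_group`, `posthoc_time`, and
#'   `simple_effects` (`NULL` unless the interaction is significant).
#' @export
analyze_scores <- function(long, alpha = 0.05) {
  wide <- long_to_wide(long)
  sph <- mendoza_sphericity(list(Y = wide$Y, group = wide$group))
  tab_raw <- mixed_anova_matrix(wide$Y, wide$group)
  tab <- if (is.finite(sph$p) && sph$p < alpha) {
    huynh_feldt_correction(tab_raw, sph$eps_hf)
  } else tab_raw

  ng <- table(wide$group)
  k <- ncol(wide$Y)
  group_means <- tapply(rowMeans(wide$Y), wide$group, mean)
  ph_group <- ryan_posthoc(group_means, n = as.numeric(ng) * k,
                           ms_error = tab$ms[tab$effect == "subjects(group)"],
                           df_error = tab$df[tab$effect == "subjects(group)"],
                           alpha = alpha)
  time_means <- colMeans(wide$Y)
  ph_time <- ryan_posthoc(time_means, n = nrow(wide$Y),
                          ms_error = tab$ms[tab$effect == "time:subjects(group)"],
                          df_error = tab$df[tab$effect == "time:subjects(group)"],
                          alpha = alpha)
  p_int <- tab$p[tab$effect == "group:time"]
  simple <- if (is.finite(p_int) && p_int < alpha) simple_main_effects(long)
    else NULL
  list(sphericity = sph, anova = tab, anova_raw = tab_raw,
       posthoc_group = ph_group, posthoc_time = ph_time,
       simple_effects = simple)
}

#' Run the reproducible end-to-end demo
#'
#' Regenerates the full synthetic experiment from one seed: a swimmer track
#' (smoothed, skeletonised, written as BVH), one manipulated stimulus bundle
#' per factorial group, a cohort of assay occupancy traces with a planted
#' Normal-group attraction, scoring with exclusion and difference scores,
#' and the complete statistical analysis. Every output file is listed in a
#' JSON manifest with its MD5 checksum, the seed and the configuration, so
#' two runs with the same seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`track`, `anim`,
#'   `bundles`, `scores`, `analysis`, `manifest`).
#' @export
run_demo <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(path) { files <<- c(files, path); path }

  sp <- do.call(swimmer_params,
                modifyList(list(seed = config$seed), config$swimmer))
  track <- smooth_moving_average(simulate_swimmer(sp))
  write_midline_csv(track, emit(file.path(out_dir, "swimmer_track.csv")))
  anim <- track_to_animation(track)

  specs <- experiment_groups(config$experiment)
  geometry <- fish_geometry(sp$body_length)
  texture <- make_rgb_fixture(32, 16, seed = config$seed + 1L)
  bundles <- lapply(names(specs), function(nm) {
    b <- apply_spec(anim, geometry, texture, specs[[nm]],
                    repeats = config$repeats)
    if (!is.null(b$animation)) {
      safe <- gsub("[^A-Za-z0-9]+", "_", nm)
      write_bvh(b$animation,
                emit(file.path(out_dir, paste0("stimulus_", safe, ".bvh"))))
    }
    b
  })
  names(bundles) <- names(specs)

  entry <- config$entry_rates
  if (is.null(entry)) entry <- make_demo_rates(config$groups)
  ap <- assay_params(n_subjects = config$n_per_group * length(config$groups),
                     groups = config$groups,
                     zone_entry_rate = entry,
                     zone_exit_rate = config$exit_rate,
                     zone_mm = config$zone_mm,
                     seed = config$seed + 2L)
  traces <- simulate_assay(ap)

  scores <- difference_scores(
    exclude_baseline(score_traces(traces, zone_mm = config$zone_mm),
                     threshold_s = config$threshold_s))
  write.csv(scores, emit(file.path(out_dir, "scores.csv")), row.names = FALSE)

  long <- scores_to_long(scores, use = "occupancy")
  analysis <- analyze_scores(long, alpha = config$alpha)
  write.csv(as.data.frame(analysis$anova),
            emit(file.path(out_dir, "anova.csv")), row.names = FALSE)
  write.csv(as.data.frame(analysis$posthoc_group),
            emit(file.path(out_dir, "posthoc_group.csv")), row.names = FALSE)
  audit <- list(
    seed = config$seed,
    sphericity = analysis$sphericity[c("statistic", "df", "p",
                                       "eps_gg", "eps_hf")],
    excluded_subjects = sum(scores$excluded))
  jsonlite::write_json(audit, emit(file.path(out_dir, "audit.json")),
                       auto_unbox = TRUE, digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("fishstim")),
    seed = config$seed,
    experiment = config$experiment,
    config = unclass(config)[c("experiment", "n_per_group", "exit_rate",
                               "zone_mm", "threshold_s", "alpha", "repeats")],
    files = lapply(sort(files), function(f)
      list(name = basename(f),
           md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(track = track, anim = anim, bundles = bundles,
                 scores = scores, analysis = analysis, manifest = manifest))
}

#' Simple body-local fish point geometry
#'
#' A coarse spindle-shaped point cloud in body-local axes (x along the body,
#' y width, z height), used as the geometry slot of stimulus bundles.
#'
#' @param body_length Body length in mm.
#' @param n Points per ring.
#' @return Numeric matrix `m x 3` (mm).
#' @export
fish_geometry <- function(body_length = 30, n = 8) {
  xs <- seq(0, 1, length.out = 11)
  radius <- 0.12 * body_length * sin(pi * pmin(1, xs * 1.15))
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  do.call(rbind, lapply(seq_along(xs), function(i) {
    cbind(-xs[i] * body_length,
          radius[i] * cos(ang) * 0.6,
          radius[i] * sin(ang))
  }))
}
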