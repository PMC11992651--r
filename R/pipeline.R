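#' @title Pipeline orchestration
#' @description End-to-end composition of the analysis stages — synthetic
#'   trajectory generation (or loading), loop metrics, SD-threshold
#'   clustering, representative selection, docked-pose scoring, and
#'   cluster-resolved energy statistics — driven by a single validated
#'   configuration with fully seeded randomness.
#' @name pipeline
NULL

#' Study-design bookkeeping
#'
#' Reproduces the sampling arithmetic of the study design: pre-docking
#' production sampling (systems x replicates x length), the docking-run
#' count (TREM2 representative structures x ApoE isoforms), post-docking
#' sampling, and the number of windowed energy records.
#'
#' @param n_predock_systems number of pre-docking systems (default 5: two
#'   TREM2 variants plus three ApoE isoforms).
#' @param n_replicates replicates per system (default 3).
#' @param predock_length_ns production length per replicate, ns (default
#'   1000).
#' @param n_trem2_structures docked TREM2 representative structures
#'   (default 6: WT-A/B/C and R47H-A/B/C).
#' @param n_isoforms ApoE isoforms (default 3).
#' @param postdock_length_ns post-docking simulation length, ns (default
#'   500).
#' @param window energy-analysis window times, default
#'   `window_frame_times(450, 500, 0.5)`.
#' @return list with predock_sampling_us, docking_runs,
#'   postdock_sampling_us, n_complexes, frames_per_complex,
#'   energy_records_total, energy_records_per_variant.
#' @export
plan_study <- function(n_predock_systems = 5, n_replicates = 3,
                       predock_length_ns = 1000, n_trem2_structures = 6,
                       n_isoforms = 3, postdock_length_ns = 500,
                       window = window_frame_times(450, 500, 0.5)) {
  n_complexes <- n_trem2_structures * n_isoforms
  frames <- length(window)
  list(
    predock_sampling_us = n_predock_systems * n_replicates *
      predock_length_ns / 1000,
    docking_runs = n_complexes,
    postdock_sampling_us = n_complexes * postdock_length_ns / 1000,
    n_complexes = n_complexes,
    frames_per_complex = frames,
    energy_records_total = n_complexes * frames,
    energy_records_per_variant = n_complexes * frames / 2
  )
}

.default_config <- function() {
  list(
    seed = 1,
    output_dir = NULL,
    window = list(t_start = 450, t_end = 500, dt = 0.5),
    contact_cutoff = 4.0,
    variants = c("WT", "R47H"),
    conformations = c("A", "B", "C"),
    isoforms = c("E2", "E3", "E4"),
    synthetic = list(
      loop = list(mu_closed = 14, mu_open = 22, sigma = 0.8,
                  switch_prob = 0.02),
      energy = list(base_mean = -30, loop_coupling = -0.8, sd = 3,
                    isoform_shift = c(E2 = 4, E3 = 2, E4 = 0),
                    variant_shift = c(WT = 0, R47H = 5)),
      pose = list(n_query_residues = 26, k_max = 18)
    )
  )
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and collects all
#' validation errors rather than failing on the first.
#'
#' @param config path to a YAML file, YAML text, or a list.
#' @return list with `config` (defaults filled) and `errors` (character
#'   vector; empty when valid).
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (length(config) == 1 && file.exists(config)) {
      yaml::read_yaml(config)
    } else {
      yaml::yaml.load(paste(config, collapse = "\n"))
    }
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  cfg <- .merge_config(.default_config(), config)
  errors <- character(0)
  w <- cfg$window
  if (!is.numeric(w$t_start) || !is.numeric(w$t_end) || !is.numeric(w$dt) ||
      w$dt <= 0 || w$t_end <= w$t_start) {
    errors <- c(errors, "window: need t_end > t_start and dt > 0")
  } else {
    k <- (w$t_end - w$t_start) / w$dt
    if (abs(k - round(k)) > 1e-9) {
      errors <- c(errors, "window: span is not an exact multiple of dt")
    }
  }
  if (!is.numeric(cfg$contact_cutoff) || cfg$contact_cutoff <= 0) {
    errors <- c(errors, "contact_cutoff: must be a positive number")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    errors <- c(errors, "seed: must be a single integer")
  }
  sl <- cfg$synthetic$loop
  if (!is.null(sl) && (!is.numeric(sl$sigma) || sl$sigma <= 0)) {
    errors <- c(errors, "synthetic.loop.sigma: must be positive")
  }
  if (!is.null(sl) && is.numeric(sl$mu_closed) && is.numeric(sl$mu_open) &&
      sl$mu_open <= sl$mu_closed) {
    errors <- c(errors, "synthetic.loop: mu_open must exceed mu_closed")
  }
  if (length(cfg$variants) == 0) errors <- c(errors, "variants: empty")
  if (length(cfg$isoforms) == 0) errors <- c(errors, "isoforms: empty")
  list(config = cfg, errors = errors)
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full synthetic analysis pipeline
#'
#' Generates one synthetic two-state loop trajectory per docked complex
#' (variant x initial conformation x isoform), computes Loop 1/Loop 2
#' series over the analysis window, fits the per-variant SD-threshold
#' cluster model (pooled over that variant's complexes), selects medoid
#' representative frames per cluster, generates and scores docked poses with
#' the CDR-vs-hinge contact filter, synthesises per-frame interaction
#' energies coupled to Loop 1, classifies them into clusters, and runs the
#' group statistics (summaries, two-way ANOVA, Tukey-Kramer,
#' occupancy-weighted means, MP clusters).
#'
#' All randomness derives from `config$seed`; the same configuration always
#' produces identical outputs. When `config$output_dir` is set, CSV/JSON
#' artifacts are written there.
#'
#' @param config a configuration list, YAML path/text, or the result of
#'   [validate_config()].
#' @param verbose log stage progress via `message()` (default FALSE).
#' @return a `run_report` list: study plan, per-stage record counts, cluster
#'   fits and occupancies, representative frames, dock ranking, group
#'   summaries, ANOVA/Tukey tables, weighted and MP-cluster energies.
#' @export
run_pipeline <- function(config = list(), verbose = FALSE) {
  val <- if (is.list(config) && identical(names(config), c("config", "errors")))
    config else validate_config(config)
  if (length(val$errors) > 0) {
    stop(paste(c("invalid configuration:", val$errors), collapse = "\n  "),
         call. = FALSE)
  }
  cfg <- val$config
  w <- cfg$window
  times <- window_frame_times(w$t_start, w$t_end, w$dt)
  n_frames <- length(times)
  complexes <- expand.grid(conformation = cfg$conformations,
                           isoform = cfg$isoforms,
                           variant = cfg$variants,
                           stringsAsFactors = FALSE)
  complexes <- complexes[, c("variant", "conformation", "isoform")]
  complexes$complex_id <- sprintf("%s-%s/%s", complexes$variant,
                                  complexes$conformation, complexes$isoform)
  n_complex <- nrow(complexes)
  .log_stage(verbose, "simulate: %d complexes x %d frames", n_complex, n_frames)

  sl <- cfg$synthetic$loop
  trajectories <- vector("list", n_complex)
  loop_tables <- vector("list", n_complex)
  for (i in seq_len(n_complex)) {
    p <- loop_dynamics_params(
      mu_closed = sl$mu_closed, mu_open = sl$mu_open, sigma = sl$sigma,
      switch_prob = sl$switch_prob, n_frames = n_frames, dt = w$dt,
      seed = cfg$seed * 1000 + i)
    # initial conformation biases the start state: A (open-like) starts open
    start <- if (complexes$conformation[i] == "A") "open" else "closed"
    sim <- generate_two_state_loop_trajectory(p, start_state = start)
    sim$trajectory$times <- sim$trajectory$times + w$t_start
    trajectories[[i]] <- sim$trajectory
    loop_tables[[i]] <- data.frame(
      complex_id = complexes$complex_id[i],
      variant = complexes$variant[i],
      conformation = complexes$conformation[i],
      isoform = complexes$isoform[i],
      time_ns = sim$trajectory$times,
      loop1 = pair_distance_series(sim$trajectory, 46, 71),
      loop2 = pair_distance_series(sim$trajectory, 67, 78),
      state = sim$states,
      stringsAsFactors = FALSE
    )
  }
  loops <- do.call(rbind, loop_tables)
  .log_stage(verbose, "loops: %d records", nrow(loops))

  # per-variant pooled cluster fits
  fits <- lapply(cfg$variants, function(v)
    loop_clusters(loops$loop1[loops$variant == v], variant = v))
  names(fits) <- cfg$variants
  loops$cluster <- NA_character_
  for (v in cfg$variants) {
    sel <- loops$variant == v
    loops$cluster[sel] <- as.character(predict(fits[[v]], loops$loop1[sel]))
  }
  occupancy <- lapply(fits, function(f) cluster_occupancy(fitted(f)))
  .log_stage(verbose, "cluster: fitted %d variants", length(fits))

  # medoid representatives per variant/cluster, from that variant's first complex
  representatives <- list()
  for (v in cfg$variants) {
    i0 <- which(complexes$variant == v)[1]
    tab <- loop_tables[[i0]]
    lab <- as.character(predict(fits[[v]], tab$loop1))
    for (cl in cfg$conformations) {
      frames <- which(lab == cl)
      if (length(frames) == 0) next
      rep_frame <- select_representative(trajectories[[i0]], frames)
      representatives[[sprintf("%s-%s", v, cl)]] <- list(
        complex_id = complexes$complex_id[i0], frame = as.integer(rep_frame),
        time_ns = trajectories[[i0]]$times[rep_frame])
    }
  }
  .log_stage(verbose, "repstruct: %d representatives", length(representatives))

  # docked-pose scoring: one synthetic pose per complex, contact count seeded
  sp <- cfg$synthetic$pose
  scores <- vector("list", n_complex)
  for (i in seq_len(n_complex)) {
    k <- .with_seed(cfg$seed * 2000 + i,
                    sample.int(min(sp$k_max, sp$n_query_residues), 1))
    pose <- generate_complex_pose(n_query_residues = sp$n_query_residues,
                                  k_in_contact = k,
                                  cutoff = cfg$contact_cutoff,
                                  seed = cfg$seed * 3000 + i)
    scores[[i]] <- cdr_hinge_fraction(pose$query, pose$target,
                                      cutoff = cfg$contact_cutoff,
                                      model_id = complexes$complex_id[i])
  }
  ranking <- rank_dock_models(scores)
  .log_stage(verbose, "dockselect: %d models, selected %s", nrow(ranking),
             attr(ranking, "selected"))

  # synthetic energies coupled to Loop 1, classified per variant
  se <- cfg$synthetic$energy
  energy_tables <- vector("list", n_complex)
  for (i in seq_len(n_complex)) {
    tab <- loop_tables[[i]]
    v <- complexes$variant[i]; iso <- complexes$isoform[i]
    noise <- .with_seed(cfg$seed * 4000 + i,
                        stats::rnorm(n_frames, 0, se$sd))
    centred <- tab$loop1 - fits[[v]]$stats$mean
    energy <- se$base_mean + se$variant_shift[[v]] + se$isoform_shift[[iso]] +
      se$loop_coupling * centred + noise
    energy_tables[[i]] <- data.frame(
      time_ns = tab$time_ns, complex_id = tab$complex_id,
      variant = v, conformation = tab$conformation, isoform = iso,
      energy = energy, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, lapply(seq_len(n_complex), function(i) {
    v <- complexes$variant[i]
    classify_energy_frames(energy_tables[[i]],
                           loop_tables[[i]][, c("time_ns", "loop1")],
                           fits[[v]]$stats)
  }))
  .log_stage(verbose, "energystats: %d records", nrow(records))

  summaries <- summarize_groups(records, c("variant", "isoform", "cluster"))
  anova_tables <- lapply(cfg$variants, function(v)
    two_way_anova(records[records$variant == v, ], "cluster", "isoform"))
  names(anova_tables) <- cfg$variants
  tukey_tables <- lapply(cfg$variants, function(v)
    tukey_kramer(records[records$variant == v, ], c("isoform", "cluster")))
  names(tukey_tables) <- cfg$variants

  pairs <- unique(records[, c("variant", "isoform")])
  ensemble <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(j) {
    s <- summaries[summaries$variant == pairs$variant[j] &
                     summaries$isoform == pairs$isoform[j], ]
    mp <- mp_cluster(s)
    data.frame(variant = pairs$variant[j], isoform = pairs$isoform[j],
               weighted_mean = weighted_cluster_mean(s),
               mp_cluster = mp$cluster, mp_mean = mp$mean, mp_n = mp$n,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    config = cfg,
    plan = plan_study(window = times),
    complexes = complexes,
    n_loop_records = nrow(loops),
    n_energy_records = nrow(records),
    records_per_variant = table(records$variant),
    fits = fits,
    occupancy = occupancy,
    representatives = representatives,
    dock_ranking = ranking,
    selected_model = attr(ranking, "selected"),
    group_summaries = summaries,
    anova = anova_tables,
    tukey = tukey_tables,
    ensemble = ensemble,
    loops = loops,
    records = records
  ), class = "run_report")

  if (!is.null(cfg$output_dir)) .write_report_files(report, cfg$output_dir)
  report
}

.write_report_files <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$loops, file.path(dir, "loop_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$records, file.path(dir, "energy_records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$group_summaries, file.path(dir, "group_summaries.csv"),
                   row.names = FALSE)
  utils::write.csv(report$dock_ranking, file.path(dir, "dock_ranking.csv"),
                   row.names = FALSE)
  json <- list(
    plan = report$plan,
    n_energy_records = report$n_energy_records,
    records_per_variant = as.list(report$records_per_variant),
    occupancy = lapply(report$occupancy, function(o)
      stats::setNames(as.list(o$fraction), o$cluster)),
    selected_model = report$selected_model,
    ensemble = report$ensemble,
    seed = report$config$seed
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report\n")
  cat(sprintf("  complexes: %d (%s variants x %s conformations x %s isoforms)\n",
              nrow(x$complexes), length(unique(x$complexes$variant)),
              length(unique(x$complexes$conformation)),
              length(unique(x$complexes$isoform))))
  cat(sprintf("  energy records: %d (%s)\n", x$n_energy_records,
              paste(sprintf("%s: %d", names(x$records_per_variant),
                            x$records_per_variant), collapse = ", ")))
  cat(sprintf("  selected dock model: %s\n", x$selected_model))
  for (v in names(x$fits)) {
    occ <- x$occupancy[[v]]
    cat(sprintf("  %s occupancy: %s\n", v,
                paste(sprintf("%s %.1f%%", occ$cluster, 100 * occ$fraction),
                      collapse = ", ")))
  }
  cat(sprintf("  ensemble weighted means (kcal/mol): %s\n",
              paste(sprintf("%s/%s %.1f", x$ensemble$variant,
                            x$ensemble$isoform, x$ensemble$weighted_mean),
                    collapse = ", ")))
  invisible(x)
}
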