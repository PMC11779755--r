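#' Pipeline run configuration
#'
#' Bundles every constant and seed of an end-to-end run. Defaults follow the
#' two study designs: the simple-shape experiment uses 10-vertex random
#' polygons (pool of 100,000), 8 k-means sample shapes, magnitudes 0.65/0.9
#' units, similarities 1.5/0.5/0.15 units, 60 stimuli and an 11-participant
#' panel; the complex experiment uses radial-frequency shapes, cube-vertex
#' exemplars, magnitudes 0.55/1.0, similarities 2.25/1.5/0.75, two groups of
#' 40 stimuli and a 20-participant panel. `pool_size` and `n_reference` can
#' be reduced for quick runs; all randomness is routed through the named
#' seeds.
#'
#' @param experiment `"simple"` or `"complex"`.
#' @param pool_size shape-pool size (default 100,000 simple / 5,000 complex).
#' @param n_reference reference-ensemble size for fitting the embedding.
#' @param n_stimuli stimuli per participant group (60 simple / 40 complex).
#' @param panel_size total synthetic participants (11 simple / 20 complex).
#' @param n_points contour resolution.
#' @param d embedding dimensionality.
#' @param constraint_mode design-sampling constraint, see [sample_design()].
#' @param magnitude_units,similarity_units unit targets per level; defaults
#'   from [design_constants()].
#' @param lambda_range fidelity range the synthetic panel is drawn from.
#' @param sigma,lengthscale contour-noise parameters of the synthetic panel.
#' @param bracket,tol calibration knobs, see [calibrate_magnitude()].
#' @param seed master seed; named stage seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(experiment = c("simple", "complex"),
                       pool_size = NULL, n_reference = 1000L,
                       n_stimuli = NULL, panel_size = NULL,
                       n_points = 100L, d = 22L,
                       constraint_mode = c("cells", "margins", "none"),
                       magnitude_units = NULL, similarity_units = NULL,
                       lambda_range = c(0.4, 0.95), sigma = 0.01,
                       lengthscale = 0.1, bracket = c(0, 4), tol = 0.01,
                       seed = 1L) {
  experiment <- match.arg(experiment)
  constraint_mode <- match.arg(constraint_mode)
  const <- design_constants(experiment)
  cfg <- list(
    experiment = experiment,
    pool_size = pool_size %||% if (experiment == "simple") 100000L else 5000L,
    n_reference = as.integer(n_reference),
    n_stimuli = n_stimuli %||% if (experiment == "simple") 60L else 40L,
    panel_size = panel_size %||% if (experiment == "simple") 11L else 20L,
    n_points = as.integer(n_points), d = as.integer(d),
    constraint_mode = constraint_mode,
    magnitude_units = magnitude_units %||% const$magnitude_units,
    similarity_units = similarity_units %||% const$similarity_units,
    lambda_range = lambda_range, sigma = sigma, lengthscale = lengthscale,
    bracket = bracket, tol = tol,
    seeds = list(pool = derive_seed(seed, 1L),
                 space = derive_seed(seed, 2L),
                 exemplars = derive_seed(seed, 3L),
                 design = derive_seed(seed, 4L),
                 participants = derive_seed(seed, 5L),
                 projection = derive_seed(seed, 6L)),
    schema_version = 1L
  )
  stopifnot(all(cfg$magnitude_units > 0), all(cfg$similarity_units > 0),
            cfg$n_stimuli <= 240L)
  structure(cfg, class = "run_config")
}

#' Run the full pipeline
#'
#' Executes fit-space, shape generation, exemplar selection, constrained
#' design sampling, trial building, panel simulation and analysis, writing
#' every artifact and a log of seeds and achieved calibrations into
#' `out_dir`. A rerun with the same configuration reproduces the same
#' numbers.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created).
#' @param figures write summary figures (PNG) as well.
#' @return invisibly, a list with the space, trials, drawings, results and
#'   summaries, plus `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, figures = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "log.txt")
  log_line <- function(...) cat(sprintf(...), "\n", file = logf, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      log_line("FAILED at stage %s: %s", name, conditionMessage(e))
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_line("experiment=%s seeds: %s", config$experiment,
           paste(names(config$seeds), unlist(config$seeds),
                 sep = "=", collapse = " "))

  pool <- stage("generate-pool", {
    if (config$experiment == "simple")
      generate_random_polygons(config$pool_size, vertices = 10L,
                               seed = config$seeds$pool)
    else
      generate_complex_shapes(config$pool_size, seed = config$seeds$pool)
  })
  space <- stage("fit-space", {
    ref_idx <- with_seed(config$seeds$space,
                         sample(length(pool), min(config$n_reference,
                                                  length(pool))))
    sp <- fit_shape_space(pool[ref_idx], d = config$d,
                          n_points = config$n_points)
    write_shape_space(sp, file.path(out_dir, "space.json"))
    sp
  })
  samples <- stage("select-samples", {
    # sample shapes must support calibration of every deformation up to the
    # highest magnitude target; candidates that cannot are screened out
    ok <- function(s) can_reach_targets(s, max(config$magnitude_units), space,
                                        bracket = config$bracket)
    if (config$experiment == "simple") {
      ex <- select_cluster_exemplars(pool, 8L, space,
                                     seed = config$seeds$exemplars,
                                     feasible = ok)
      log_line("sample pool indices: %s",
               paste(attr(ex, "pool_index"), collapse = ","))
      ex
    } else {
      sel <- generate_complex_shapes(config$pool_size,
                                     seed = config$seeds$pool, space = space,
                                     feasible = ok)
      log_line("cube exemplar indices: %s (cost %.3f)",
               paste(sel$exemplar_idx, collapse = ","), sel$assignment_cost)
      pool <<- sel$shapes
      sel$shapes[sel$exemplar_idx]
    }
  })

  conditions <- enumerate_design(8L)
  groups <- stage("sample-design", {
    if (config$experiment == "simple") {
      list(sample_design(conditions, config$n_stimuli,
                         config$constraint_mode, seed = config$seeds$design))
    } else {
      # two observer groups with different stimulus sets; joint coverage of
      # every factor level at least twice is checked over the union
      g1 <- sample_design(conditions, config$n_stimuli, "margins",
                          seed = config$seeds$design)
      g2 <- sample_design(conditions, config$n_stimuli, "margins",
                          seed = derive_seed(config$seeds$design, 2L))
      un <- rbind(g1, g2)
      for (f in c("type", "magnitude", "similarity"))
        stopifnot(all(table(un[[f]]) >= 2L))
      list(g1, g2)
    }
  })

  trials_by_group <- stage("build-trials", {
    out <- list()
    offset <- 0L
    for (g in seq_along(groups)) {
      tr <- build_trials(groups[[g]], samples, pool, space,
                         magnitude_units = config$magnitude_units,
                         similarity_units = config$similarity_units,
                         n_points = config$n_points,
                         bracket = config$bracket, tol = config$tol)
      for (i in seq_along(tr)) tr[[i]]$trial_id <- tr[[i]]$trial_id + offset
      offset <- offset + length(tr)
      out[[g]] <- tr
    }
    write_stimulus_set(do.call(c, out), file.path(out_dir, "stimuli"))
    for (tr in out[[1]])
      log_line("trial %d: %s %s calibrated raw=%.5f achieved=%.4f units",
               tr$trial_id, tr$type, tr$magnitude_level,
               tr$spec$raw_param, tr$spec$calibrated_units)
    out
  })

  drawings <- stage("simulate-panel", {
    per_group <- length(groups)
    psize <- config$panel_size %/% per_group
    all <- list()
    pid0 <- 0L
    for (g in seq_along(groups)) {
      panel <- with_seed(derive_seed(config$seeds$participants, g), {
        lapply(seq_len(psize), function(p)
          participant_model(
            lambda = stats::runif(1, config$lambda_range[1],
                                  config$lambda_range[2]),
            sigma = config$sigma, lengthscale = config$lengthscale,
            seed = derive_seed(config$seeds$participants, g * 100L + p)))
      })
      dr <- simulate_experiment(trials_by_group[[g]], panel)
      dr$participant_id <- dr$participant_id + pid0
      pid0 <- pid0 + psize
      all[[g]] <- dr
    }
    dr <- do.call(rbind, all)
    ddir <- file.path(out_dir, "drawings")
    dir.create(ddir, showWarnings = FALSE)
    files <- character(nrow(dr))
    for (i in seq_len(nrow(dr))) {
      files[i] <- sprintf("p%02d_trial%03d.csv", dr$participant_id[i],
                          dr$trial_id[i])
      write_contour_csv(dr$drawing[[i]], file.path(ddir, files[i]))
    }
    manifest <- data.frame(participant_id = dr$participant_id,
                           trial_id = dr$trial_id, lambda = dr$lambda,
                           sigma = dr$sigma, file = file.path("drawings", files))
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    dr
  })

  trials <- do.call(c, trials_by_group)
  results <- stage("analyze", {
    res <- score_experiment(drawings, trials, space)
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    res
  })
  summaries <- stage("aggregate", {
    s <- list()
    for (g in c("overall", "by_type", "by_similarity", "by_magnitude")) {
      s[[g]] <- tryCatch(suppressWarnings(aggregate_diffs(results, g)),
                         error = function(e) {
                           log_line("aggregation %s skipped: %s", g,
                                    conditionMessage(e))
                           NULL
                         })
    }
    s <- Filter(Negate(is.null), s)
    tab <- do.call(rbind, lapply(names(s), function(nm) {
      g <- s[[nm]]$groups
      g$grouping <- nm
      g
    }))
    if (!is.null(tab))
      utils::write.csv(tab, file.path(out_dir, "summary.csv"), row.names = FALSE)
    s
  })
  if (figures) {
    stage("visualize", {
      gp <- plot_condition_means(summaries$by_type)
      grDevices::png(file.path(out_dir, "fig_by_type.png"), 900, 600, res = 120)
      print(gp)
      grDevices::dev.off()
      sel <- seq_len(min(40L, nrow(drawings)))
      shapes <- c(lapply(trials[1:2], `[[`, "test"),
                  lapply(trials[1:2], `[[`, "transformed_test"),
                  drawings$drawing[sel])
      xy <- project_2d(shapes, space, seed = config$seeds$projection)
      grDevices::png(file.path(out_dir, "fig_shape_map.png"), 700, 700, res = 120)
      print(plot_shape_map(xy, c(rep("test", 2), rep("transformed test", 2),
                                 rep("drawing", length(sel)))))
      grDevices::dev.off()
    })
  }
  log_line("done: %d drawings, %d trials", nrow(drawings), length(trials))
  invisible(list(config = config, space = space, trials = trials,
                 drawings = drawings, results = results,
                 summaries = summaries, out_dir = out_dir))
}
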