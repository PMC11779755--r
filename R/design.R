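#' Design constants for the simple- and complex-shape experiments
#'
#' Transformation magnitudes and sample-test similarity levels, expressed as
#' distances in similarity units. Higher similarity means a *smaller*
#' distance, so the "high" similarity level carries the smallest unit value.
#'
#' @param experiment `"simple"` or `"complex"`.
#' @return list with `magnitude_units` (named low/high) and
#'   `similarity_units` (named low/medium/high).
#' @export
design_constants <- function(experiment = c("simple", "complex")) {
  experiment <- match.arg(experiment)
  if (experiment == "simple")
    list(magnitude_units = c(low = 0.65, high = 0.9),
         similarity_units = c(low = 1.5, medium = 0.5, high = 0.15))
  else
    list(magnitude_units = c(low = 0.55, high = 1.0),
         similarity_units = c(low = 2.25, medium = 1.5, high = 0.75))
}

#' Full factorial design enumeration
#'
#' Crosses sample shapes, transformation types, magnitude levels and
#' sample-test similarity levels into one row per condition, in
#' lexicographic order. The canonical design (8 samples x 5 types x
#' 2 magnitudes x 3 similarities) has 240 rows.
#'
#' @param samples number of sample shapes (or a vector of sample ids).
#' @param types transformation types.
#' @param magnitudes magnitude level labels.
#' @param similarities similarity level labels.
#' @return data frame with columns `sample_id`, `type`, `magnitude`,
#'   `similarity`.
#' @export
enumerate_design <- function(samples = 8L,
                             types = transform_kinds(),
                             magnitudes = c("low", "high"),
                             similarities = c("low", "medium", "high")) {
  ids <- if (length(samples) == 1L && is.numeric(samples))
    seq_len(samples) else samples
  g <- expand.grid(similarity = similarities, magnitude = magnitudes,
                   type = types, sample_id = ids,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("sample_id", "type", "magnitude", "similarity")]
  g <- g[order(g$sample_id, g$type, g$magnitude, g$similarity), ]
  rownames(g) <- NULL
  g
}

#' Constrained random sampling of the factorial design
#'
#' Draws `n_stimuli` conditions from the enumerated design under a coverage
#' constraint. In `"cells"` mode every (type x magnitude x similarity) cell
#' must be selected at least twice — with 30 cells and the standard budget of
#' 60 stimuli this forces exactly two per cell, with the sample-shape
#' assignment randomized. In `"margins"` mode each level of each of the
#' three factors must appear at least twice; subsets are redrawn until the
#' constraint holds (bounded retries, then constructive repair by swapping in
#' rows that cover missing levels).
#'
#' @param conditions design data frame from [enumerate_design()].
#' @param n_stimuli number of rows to select.
#' @param constraint_mode `"cells"` (default), `"margins"`, or `"none"` for an
#'   unconstrained uniform draw (minimal debug runs).
#' @param seed integer seed.
#' @param max_retries rejection-sampling bound for margins mode.
#' @return data frame of selected condition rows.
#' @export
sample_design <- function(conditions, n_stimuli,
                          constraint_mode = c("cells", "margins", "none"),
                          seed = 1L, max_retries = 200L) {
  constraint_mode <- match.arg(constraint_mode)
  if (n_stimuli > nrow(conditions))
    stop("n_stimuli exceeds the number of conditions")
  cell_key <- interaction(conditions$type, conditions$magnitude,
                          conditions$similarity, drop = TRUE)
  if (constraint_mode == "none") {
    sel <- with_seed(seed, sort(sample(nrow(conditions), n_stimuli)))
  } else if (constraint_mode == "cells") {
    ncell <- nlevels(cell_key)
    if (n_stimuli < 2L * ncell)
      stop(sprintf("infeasible: %d stimuli cannot cover %d cells twice",
                   n_stimuli, ncell))
    sel <- with_seed(seed, {
      base <- unlist(lapply(split(seq_len(nrow(conditions)), cell_key),
                            function(ix) sample(ix, 2L)))
      extra <- n_stimuli - length(base)
      if (extra > 0) {
        rest <- setdiff(seq_len(nrow(conditions)), base)
        base <- c(base, sample(rest, extra))
      }
      sort(base)
    })
  } else {
    need <- max(vapply(conditions[c("type", "magnitude", "similarity")],
                       function(f) length(unique(f)), integer(1))) * 2L
    if (n_stimuli < need)
      stop(sprintf("infeasible: %d stimuli cannot cover each level twice",
                   n_stimuli))
    covered <- function(ix) {
      sub <- conditions[ix, ]
      all(vapply(c("type", "magnitude", "similarity"), function(f) {
        tb <- table(factor(sub[[f]], levels = unique(conditions[[f]])))
        all(tb >= 2L)
      }, logical(1)))
    }
    sel <- with_seed(seed, {
      ix <- NULL
      for (try in seq_len(max_retries)) {
        ix <- sample(nrow(conditions), n_stimuli)
        if (covered(ix)) break
        ix <- NULL
      }
      if (is.null(ix)) {   # constructive repair
        ix <- sample(nrow(conditions), n_stimuli)
        for (f in c("type", "magnitude", "similarity")) {
          lev <- unique(conditions[[f]])
          repeat {
            tb <- table(factor(conditions[[f]][ix], levels = lev))
            short <- names(tb)[tb < 2L]
            if (!length(short)) break
            donor_lvls <- names(tb)[tb > 2L]
            out_pos <- which(conditions[[f]][ix] %in% donor_lvls)[1]
            in_row <- setdiff(which(conditions[[f]] == short[1]), ix)[1]
            ix[out_pos] <- in_row
          }
        }
        if (!covered(ix)) stop("constraint repair failed")
      }
      sort(ix)
    })
  }
  out <- conditions[sel, ]
  rownames(out) <- NULL
  out
}

#' Build stimulus trials from a sampled design
#'
#' For each selected condition: calibrates the transformation on the sample
#' shape so that it moves the sample by the magnitude level's unit target,
#' constructs the transformed sample, selects a test shape from the pool at
#' the similarity level's target distance from the sample, and applies the
#' *same* calibrated spec to the test to obtain the ground-truth transformed
#' test (never shown to a participant). Calibrations and test selections are
#' cached across rows sharing the same (sample, type, magnitude) or
#' (sample, similarity) combination.
#'
#' @param design data frame from [sample_design()].
#' @param samples list of sample [contour()]s indexed by `sample_id`.
#' @param pool list of candidate test shapes.
#' @param space a fitted [fit_shape_space()].
#' @param magnitude_units named vector of unit targets per magnitude level.
#' @param similarity_units named vector of unit targets per similarity level.
#' @param n_points contour resolution used for all trial shapes.
#' @param bracket,tol passed to [calibrate_magnitude()].
#' @return list of `stimulus_trial` objects.
#' @export
build_trials <- function(design, samples, pool, space,
                         magnitude_units = design_constants("simple")$magnitude_units,
                         similarity_units = design_constants("simple")$similarity_units,
                         n_points = 100L, bracket = c(0, 4), tol = 0.01) {
  samples <- lapply(samples, function(s)
    resample_uniform(normalize_contour(as_contour(s)), n_points))
  pool_emb <- t(vapply(pool, function(s) embed_contour(space, s),
                       numeric(space$d)))
  spec_cache <- new.env(parent = emptyenv())
  test_cache <- new.env(parent = emptyenv())
  lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    sm <- samples[[row$sample_id]]
    skey <- paste(row$sample_id, row$type, row$magnitude, sep = "|")
    spec <- if (!is.null(spec_cache[[skey]])) spec_cache[[skey]] else {
      sp <- tryCatch(
        calibrate_magnitude(sm, row$type, magnitude_units[[row$magnitude]],
                            space, bracket = bracket, tol = tol),
        error = function(e) stop(sprintf(
          "trial %d (sample %d, %s, %s magnitude): %s",
          i, row$sample_id, row$type, row$magnitude, conditionMessage(e)),
          call. = FALSE))
      spec_cache[[skey]] <- sp
      sp
    }
    tkey <- paste(row$sample_id, row$similarity, sep = "|")
    test <- if (!is.null(test_cache[[tkey]])) test_cache[[tkey]] else {
      es <- embed_contour(space, sm)
      dall <- sqrt(rowSums(sweep(pool_emb, 2, es)^2))
      cand <- which(dall > 1e-12)
      j <- cand[which.min(abs(dall[cand] - similarity_units[[row$similarity]]))]
      tt <- resample_uniform(normalize_contour(pool[[j]]), n_points)
      attr(tt, "achieved_units") <- dall[j]
      attr(tt, "pool_index") <- j
      test_cache[[tkey]] <- tt
      tt
    }
    structure(list(
      trial_id = i,
      sample_id = row$sample_id,
      type = row$type,
      magnitude_level = row$magnitude,
      magnitude_units = unname(magnitude_units[[row$magnitude]]),
      similarity_level = row$similarity,
      similarity_units = unname(similarity_units[[row$similarity]]),
      achieved_similarity = attr(test, "achieved_units"),
      spec = spec,
      sample = sm,
      transformed_sample = apply_transform(sm, spec),
      test = test,
      transformed_test = apply_transform(test, spec),
      start_marker_index = 1L
    ), class = "stimulus_trial")
  })
}

#' @export
print.stimulus_trial <- function(x, ...) {
  cat(sprintf(
    "<stimulus_trial %d: sample %d, %s (%s magnitude, %.2f units), %s similarity>\n",
    x$trial_id, x$sample_id, x$type, x$magnitude_level,
    x$spec$calibrated_units, x$similarity_level))
  invisible(x)
}
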