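#' Difference-of-distances statistic for one drawing
#'
#' Computes the two critical distances for a drawing — to the untransformed
#' test shape and to the ground-truth transformed test — and their difference
#' `diff = dissim(drawing, transformed test) - dissim(drawing, test)`.
#' Negative values indicate that the drawing resembles the transformed test
#' more, i.e. the transformation was inferred and reproduced. Both distances
#' are measured after normalization, which matches the centers (and scales)
#' of drawing and targets. A degenerate drawing yields a flagged-invalid
#' result with `NA` distances rather than an error, so it can be excluded
#' from aggregation.
#'
#' @param drawing a [contour()].
#' @param trial the `stimulus_trial` the drawing responds to.
#' @param space a fitted [fit_shape_space()].
#' @param participant_id optional id copied into the result.
#' @return one-row data frame: ids, factor levels, `d_test`,
#'   `d_transformed`, `diff`, `valid`.
#' @export
trial_diff <- function(drawing, trial, space, participant_id = NA_integer_) {
  emb <- tryCatch(embed_contour(space, drawing), error = function(e) NULL)
  if (is.null(emb)) {
    d_test <- d_tr <- NA_real_
  } else {
    d_test <- sqrt(sum((emb - embed_contour(space, trial$test))^2))
    d_tr <- sqrt(sum((emb - embed_contour(space, trial$transformed_test))^2))
  }
  data.frame(
    trial_id = trial$trial_id,
    participant_id = participant_id,
    type = trial$type,
    magnitude_level = trial$magnitude_level,
    similarity_level = trial$similarity_level,
    d_test = d_test,
    d_transformed = d_tr,
    diff = d_tr - d_test,
    valid = !is.null(emb)
  )
}

#' Score a simulated (or loaded) experiment
#'
#' Applies [trial_diff()] to every row of a drawings table from
#' [simulate_experiment()].
#'
#' @param drawings data frame with `participant_id`, `trial_id` and a
#'   `drawing` list-column.
#' @param trials the `stimulus_trial` list the drawings respond to.
#' @param space a fitted [fit_shape_space()].
#' @return data frame of trial results, one row per drawing.
#' @export
score_experiment <- function(drawings, trials, space) {
  tmap <- stats::setNames(seq_along(trials),
                          vapply(trials, `[[`, numeric(1), "trial_id"))
  # embed each distinct test / transformed test once
  emb_test <- lapply(trials, function(t) embed_contour(space, t$test))
  emb_tr <- lapply(trials, function(t) embed_contour(space, t$transformed_test))
  res <- lapply(seq_len(nrow(drawings)), function(i) {
    tr <- trials[[tmap[[as.character(drawings$trial_id[i])]]]]
    j <- tmap[[as.character(drawings$trial_id[i])]]
    emb <- tryCatch(embed_contour(space, drawings$drawing[[i]]),
                    error = function(e) NULL)
    d_test <- if (is.null(emb)) NA_real_ else sqrt(sum((emb - emb_test[[j]])^2))
    d_tr <- if (is.null(emb)) NA_real_ else sqrt(sum((emb - emb_tr[[j]])^2))
    data.frame(trial_id = tr$trial_id,
               participant_id = drawings$participant_id[i],
               type = tr$type,
               magnitude_level = tr$magnitude_level,
               similarity_level = tr$similarity_level,
               d_test = d_test, d_transformed = d_tr,
               diff = d_tr - d_test, valid = !is.null(emb))
  })
  do.call(rbind, res)
}

#' Aggregate trial results
#'
#' Reproduces the standard aggregation of the difference statistic: per
#' group, the mean `diff` with a t-based 95% confidence interval and a
#' two-sided one-sample t test against zero; across groups, a one-way F test
#' (`by_type`, `by_similarity`) or a two-sample t test across the two levels
#' (`by_magnitude`; Welch by default, pooled variance available). With N
#' pooled trials the one-sample df is N - 1 and the one-way F df are
#' (k - 1, N - k). A Holm-corrected column accompanies the per-group
#' p-values. Invalid results are excluded with a warning.
#'
#' @param results data frame from [score_experiment()] / [trial_diff()].
#' @param grouping one of `"overall"`, `"by_type"`, `"by_similarity"`,
#'   `"by_magnitude"`.
#' @param conf_level confidence level for the intervals.
#' @param var_equal pooled-variance two-sample t for the magnitude contrast.
#' @return object of class `diff_summary`: list with `grouping`, `groups`
#'   (data frame) and `omnibus` (NULL, F test, or two-sample t).
#' @export
aggregate_diffs <- function(results,
                            grouping = c("overall", "by_type",
                                         "by_similarity", "by_magnitude"),
                            conf_level = 0.95, var_equal = FALSE) {
  grouping <- match.arg(grouping)
  if (any(!results$valid)) {
    warning(sprintf("excluding %d invalid results", sum(!results$valid)))
    results <- results[results$valid, ]
  }
  gvar <- switch(grouping, overall = NULL, by_type = "type",
                 by_similarity = "similarity_level",
                 by_magnitude = "magnitude_level")
  groups <- if (is.null(gvar)) list(overall = results)
            else split(results, results[[gvar]])
  if (any(vapply(groups, nrow, integer(1)) < 2)) {
    empty <- names(groups)[vapply(groups, nrow, integer(1)) < 2]
    warning("omitting groups with fewer than 2 results: ",
            paste(empty, collapse = ", "))
    groups <- groups[vapply(groups, nrow, integer(1)) >= 2]
  }
  if (!length(groups)) stop("no groups with at least 2 valid results")
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]$diff
    if (stats::sd(x) < 1e-14)
      stop(sprintf("degenerate variance in group '%s': all diffs equal", g))
    tt <- stats::t.test(x, mu = 0, conf.level = conf_level)
    data.frame(group = g, n = length(x), mean_diff = mean(x),
               sd = stats::sd(x),
               ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  tab <- do.call(rbind, rows)
  tab$p_holm <- stats::p.adjust(tab$p, method = "holm")
  omnibus <- NULL
  if (grouping %in% c("by_type", "by_similarity")) {
    dat <- do.call(rbind, groups)
    y <- dat$diff
    fac <- factor(dat[[gvar]])
    f <- stats::oneway.test(y ~ fac, var.equal = TRUE)
    omnibus <- list(test = "one-way F", F = unname(f$statistic),
                    df1 = unname(f$parameter[1]), df2 = unname(f$parameter[2]),
                    p = f$p.value)
  } else if (grouping == "by_magnitude" && length(groups) == 2) {
    tt <- stats::t.test(groups[[1]]$diff, groups[[2]]$diff,
                        var.equal = var_equal)
    omnibus <- list(test = if (var_equal) "two-sample t (pooled)"
                           else "two-sample t (Welch)",
                    t = unname(tt$statistic), df = unname(tt$parameter),
                    p = tt$p.value,
                    levels = names(groups))
  }
  structure(list(grouping = grouping, groups = tab, omnibus = omnibus,
                 conf_level = conf_level),
            class = "diff_summary")
}

#' @export
print.diff_summary <- function(x, ...) {
  cat(sprintf("Difference-of-distances summary (%s)\n", x$grouping))
  print(x$groups, row.names = FALSE, digits = 4)
  if (!is.null(x$omnibus)) {
    o <- x$omnibus
    if (o$test == "one-way F")
      cat(sprintf("%s: F(%d, %d) = %.3f, p = %.4g\n",
                  o$test, o$df1, o$df2, o$F, o$p))
    else
      cat(sprintf("%s: t(%.1f) = %.3f, p = %.4g\n", o$test, o$df, o$t, o$p))
  }
  invisible(x)
}

#' Fidelity recovery experiment
#'
#' Sanity harness for the whole pipeline: simulates panels of synthetic
#' participants at each fidelity level in `lambda_grid` and reports the
#' overall mean difference statistic with its confidence interval and test.
#' The mean diff should decrease monotonically in fidelity, positive at
#' `lambda = 0` (drawings copy the test) and negative at `lambda = 1`
#' (drawings reproduce the transformation).
#'
#' @param lambda_grid fidelity values in \[0, 1\].
#' @param panel_size synthetic participants per fidelity level.
#' @param trials `stimulus_trial` list.
#' @param space a fitted [fit_shape_space()].
#' @param sigma contour noise level for all participants.
#' @param seed integer seed.
#' @return data frame, one row per fidelity level, sorted by `lambda`.
#' @export
recovery_experiment <- function(lambda_grid, panel_size, trials, space,
                                sigma = 0.01, seed = 1L) {
  stopifnot(all(lambda_grid >= 0 & lambda_grid <= 1))
  lambda_grid <- sort(lambda_grid)
  out <- lapply(seq_along(lambda_grid), function(k) {
    lam <- lambda_grid[k]
    panel <- lapply(seq_len(panel_size), function(p)
      participant_model(lambda = lam, sigma = sigma,
                        seed = derive_seed(seed, k * 1000L + p)))
    dr <- simulate_experiment(trials, panel)
    res <- score_experiment(dr, trials, space)
    agg <- aggregate_diffs(res, "overall")
    g <- agg$groups
    data.frame(lambda = lam, n = g$n, mean_diff = g$mean_diff,
               ci_lo = g$ci_lo, ci_hi = g$ci_hi, t = g$t, df = g$df, p = g$p,
               sign = sign(g$mean_diff))
  })
  do.call(rbind, out)
}
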