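#' Contour readers and writers
#'
#' The CSV dialect is two columns `x,y` with a header, one row per vertex.
#' The JSON dialect is `{"points": [[x, y], ...], "meta": ...}`. Round-trips
#' preserve coordinates exactly at full double precision.
#'
#' @param c a [contour()].
#' @param path file path.
#' @return readers return a `contour`; writers return `path` invisibly.
#' @export
write_contour_csv <- function(c, path) {
  p <- as_contour(c)
  # full double precision so round-trips are exact
  lines <- c("x,y", sprintf("%.17g,%.17g", p[, 1], p[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_csv <- function(path) {
  d <- utils::read.csv(path)
  contour(as.matrix(d[, c("x", "y")]))
}

#' @rdname write_contour_csv
#' @export
write_contour_json <- function(c, path) {
  p <- as_contour(c)
  obj <- list(points = lapply(seq_len(nrow(p)),
                              function(i) c(p[i, 1], p[i, 2])),
              meta = attr(p, "meta"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contour_csv
#' @export
read_contour_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (!is.matrix(pts)) pts <- do.call(rbind, pts)
  contour(pts, meta = obj$meta)
}

#' Export contours as an SVG drawing
#'
#' Writes one or more contours as closed `<path>` elements for visual
#' inspection (y axis flipped so the canvas convention matches the screen).
#'
#' @param contours a contour or list of contours.
#' @param path output file.
#' @param size viewBox side length.
#' @param stroke stroke colors, recycled.
#' @return `path`, invisibly.
#' @export
write_contours_svg <- function(contours, path, size = 512,
                               stroke = c("#1b6ca8", "#c0392b", "#27ae60",
                                          "#8e44ad", "#f39c12")) {
  if (inherits(contours, "contour")) contours <- list(contours)
  stroke <- rep_len(stroke, length(contours))
  paths <- vapply(seq_along(contours), function(i) {
    p <- unclass(as_contour(contours[[i]]))[, 1:2]
    xy <- cbind((p[, 1] + 0.5) * size, (0.5 - p[, 2]) * size)
    d <- paste0("M ", paste(sprintf("%.3f %.3f", xy[, 1], xy[, 2]),
                            collapse = " L "), " Z")
    sprintf('  <path d="%s" fill="none" stroke="%s" stroke-width="1.5"/>',
            d, stroke[i])
  }, character(1))
  lines <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %d %d">',
                     size, size),
             paths, "</svg>")
  writeLines(lines, path)
  invisible(path)
}

#' Transform-spec serialization
#'
#' @param spec a [transform_spec()].
#' @param path file path.
#' @return the spec (readers) or `path` invisibly (writers).
#' @export
write_transform_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_spec(o$kind, o$raw_param, o$target_units %||% NA_real_,
                 o$calibrated_units %||% NA_real_)
}

#' Persist and restore a fitted shape space
#'
#' The space is written as a single JSON bundle carrying the descriptor
#' roster version; loading refuses a bundle whose roster version does not
#' match the installed one.
#'
#' @param space a [fit_shape_space()] result.
#' @param path file path.
#' @return the space (reader) or `path` invisibly (writer).
#' @export
write_shape_space <- function(space, path) {
  obj <- space
  obj$projection <- list(values = as.vector(space$projection),
                         nrow = nrow(space$projection),
                         dimnames = rownames(space$projection))
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_shape_space
#' @export
read_shape_space <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(o$roster_version, descriptor_roster_version))
    stop(sprintf("descriptor roster mismatch: bundle is %s, installed is %s",
                 o$roster_version, descriptor_roster_version))
  proj <- matrix(o$projection$values, nrow = o$projection$nrow)
  rownames(proj) <- o$projection$dimnames
  structure(list(
    roster_version = o$roster_version,
    descriptor_names = o$descriptor_names,
    means = stats::setNames(unlist(o$means), o$descriptor_names),
    sds = stats::setNames(unlist(o$sds), o$descriptor_names),
    projection = proj,
    d = o$d, n_points = o$n_points,
    unit_scale = o$unit_scale, n_reference = o$n_reference,
    orientation_sensitive = o$orientation_sensitive
  ), class = "shape_space")
}

#' Write and read a stimulus set directory
#'
#' Serializes a trial list as `trials.json` (specs, factor levels, ids,
#' achieved calibrations) plus one contour CSV per shape role, so a stimulus
#' set can be inspected, archived and re-loaded to equal trials.
#'
#' @param trials list of `stimulus_trial`s.
#' @param dir directory (created if missing).
#' @return the trial list (reader) or `dir` invisibly (writer).
#' @export
write_stimulus_set <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- lapply(trials, function(tr) {
    base <- sprintf("trial%03d", tr$trial_id)
    for (role in c("sample", "transformed_sample", "test", "transformed_test"))
      write_contour_csv(tr[[role]], file.path(dir, paste0(base, "_", role, ".csv")))
    list(trial_id = tr$trial_id, sample_id = tr$sample_id, type = tr$type,
         magnitude_level = tr$magnitude_level,
         magnitude_units = tr$magnitude_units,
         similarity_level = tr$similarity_level,
         similarity_units = tr$similarity_units,
         achieved_similarity = tr$achieved_similarity,
         spec = unclass(tr$spec),
         start_marker_index = tr$start_marker_index,
         files = paste0(base, "_",
                        c("sample", "transformed_sample", "test",
                          "transformed_test"), ".csv"))
  })
  jsonlite::write_json(meta, file.path(dir, "trials.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_stimulus_set
#' @export
read_stimulus_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "trials.json"),
                              simplifyVector = FALSE)
  lapply(meta, function(m) {
    shapes <- lapply(m$files, function(f) read_contour_csv(file.path(dir, f)))
    structure(list(
      trial_id = m$trial_id, sample_id = m$sample_id, type = m$type,
      magnitude_level = m$magnitude_level,
      magnitude_units = m$magnitude_units,
      similarity_level = m$similarity_level,
      similarity_units = m$similarity_units,
      achieved_similarity = m$achieved_similarity,
      spec = transform_spec(m$spec$kind, m$spec$raw_param,
                            m$spec$target_units %||% NA_real_,
                            m$spec$calibrated_units %||% NA_real_),
      sample = shapes[[1]], transformed_sample = shapes[[2]],
      test = shapes[[3]], transformed_test = shapes[[4]],
      start_marker_index = m$start_marker_index
    ), class = "stimulus_trial")
  })
}
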