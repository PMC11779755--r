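#' Synthetic participant model
#'
#' A generative stand-in for a human drawer. The participant reproduces a
#' blend between the test shape and the ground-truth transformed test, with
#' smooth periodic contour noise:
#' fidelity `lambda = 0` copies the test, `lambda = 1` applies the observed
#' transformation perfectly. Contour noise is a per-coordinate stationary
#' Gaussian process along the closed contour with a squared-exponential
#' kernel, synthesized spectrally so the drawn curve stays closed.
#'
#' @param lambda fidelity in \[0, 1\].
#' @param sigma contour noise standard deviation, normalized-canvas units.
#' @param lengthscale noise correlation length as a fraction of the perimeter,
#'   in (0, 1).
#' @param closure_jitter endpoint gap (canvas units on the 2048 canvas) added
#'   when the drawing is exported as a raw trace.
#' @param seed integer seed for the participant's noise stream.
#' @return an object of class `participant_model`.
#' @export
participant_model <- function(lambda = 0.75, sigma = 0.01, lengthscale = 0.1,
                              closure_jitter = 0, seed = 1L) {
  stopifnot(lambda >= 0, lambda <= 1, sigma >= 0,
            lengthscale > 0, lengthscale < 1, closure_jitter >= 0)
  structure(list(lambda = lambda, sigma = sigma, lengthscale = lengthscale,
                 closure_jitter = closure_jitter, seed = as.integer(seed)),
            class = "participant_model")
}

#' @export
print.participant_model <- function(x, ...) {
  cat(sprintf(
    "<participant_model: lambda=%.2f, sigma=%.3f, lengthscale=%.2f, seed=%d>\n",
    x$lambda, x$sigma, x$lengthscale, x$seed))
  invisible(x)
}

# Smooth periodic noise: spectral synthesis of a stationary GP on the circle
# with squared-exponential covariance of lengthscale ell (fraction of the
# period), scaled to pointwise standard deviation sigma. Returns an n-vector.
periodic_gp_noise <- function(n, sigma, ell, n_harmonics = 32L) {
  if (sigma <= 0) return(numeric(n))
  k <- seq_len(n_harmonics)
  w <- exp(-2 * (pi * k * ell)^2)          # spectral weights of the SE kernel
  w <- w / sqrt(sum(w^2))
  a <- stats::rnorm(n_harmonics)
  b <- stats::rnorm(n_harmonics)
  t <- (0:(n - 1)) / n
  drop(cos(2 * pi * outer(t, k)) %*% (w * a) +
       sin(2 * pi * outer(t, k)) %*% (w * b)) * sigma
}

#' Simulate one drawing for a trial
#'
#' The synthetic drawing is
#' `normalize((1 - lambda) * test + lambda * transformed_test + noise)`.
#' The blend relies on the index correspondence between test and transformed
#' test (both are traced clockwise from the start marker, as the drawing task
#' enforces), and the drawing keeps that correspondence; uniform arc-length
#' resampling happens inside descriptor extraction, so a noise-free
#' perfect-fidelity drawing is scored exactly like the transformed test
#' itself. Noise large enough to self-intersect is permitted — humans
#' scribble — and only noted via the `"simple"` attribute.
#'
#' @param trial a `stimulus_trial` from [build_trials()].
#' @param model a [participant_model()].
#' @param stream optional extra integer mixed into the noise seed so one
#'   participant draws independently across trials.
#' @return a normalized, uniformly resampled [contour()].
#' @export
simulate_drawing <- function(trial, model, stream = trial$trial_id) {
  test <- trial$test
  tt <- trial$transformed_test
  if (nrow(test) != nrow(tt))
    stop("test and transformed test must share point correspondence")
  n <- nrow(test)
  lam <- model$lambda
  pts <- (1 - lam) * unclass(test)[, 1:2] + lam * unclass(tt)[, 1:2]
  if (model$sigma > 0) {
    eps <- with_seed(derive_seed(model$seed, stream), cbind(
      periodic_gp_noise(n, model$sigma, model$lengthscale),
      periodic_gp_noise(n, model$sigma, model$lengthscale)))
    pts <- pts + eps
  }
  d <- normalize_contour(contour(pts))
  attr(d, "simple") <- is_simple_polygon(d)
  attr(d, "meta") <- sprintf("drawing_trial%d", trial$trial_id)
  d
}

#' Simulate a panel of participants over a stimulus set
#'
#' One drawing per (participant x trial); the standard simple-shape run of 11
#' participants by 60 stimuli yields 660 drawings, the complex run of 20 by
#' 40 yields 800. Deterministic given the participants' seeds.
#'
#' @param trials list of `stimulus_trial`s.
#' @param panel list of [participant_model()]s.
#' @return data frame with columns `participant_id`, `trial_id`, `lambda`,
#'   `sigma`, and a list-column `drawing` of contours.
#' @export
simulate_experiment <- function(trials, panel) {
  stopifnot(length(trials) >= 1, length(panel) >= 1)
  rows <- vector("list", length(panel) * length(trials))
  k <- 0L
  for (p in seq_along(panel)) {
    for (t in seq_along(trials)) {
      k <- k + 1L
      rows[[k]] <- list(participant_id = p,
                        trial_id = trials[[t]]$trial_id,
                        lambda = panel[[p]]$lambda,
                        sigma = panel[[p]]$sigma,
                        drawing = simulate_drawing(trials[[t]], panel[[p]]))
    }
  }
  data.frame(
    participant_id = vapply(rows, `[[`, integer(1), "participant_id"),
    trial_id = vapply(rows, `[[`, numeric(1), "trial_id"),
    lambda = vapply(rows, `[[`, numeric(1), "lambda"),
    sigma = vapply(rows, `[[`, numeric(1), "sigma"),
    drawing = I(lapply(rows, `[[`, "drawing"))
  )
}

#' Export a drawing as a raw canvas trace
#'
#' Scales a normalized drawing onto a square canvas (default 2048 units,
#' emulating the tablet) and appends a final point displaced by the
#' participant's closure jitter, producing the raw open trace a drawing UI
#' would record. [is_closed()] applied to the result reproduces the
#' green-light closure check.
#'
#' @param drawing a normalized [contour()].
#' @param model a [participant_model()] (supplies `closure_jitter`).
#' @param canvas canvas side length in canvas units.
#' @return a matrix of raw points in canvas units (y down).
#' @export
as_raw_trace <- function(drawing, model, canvas = 2048) {
  p <- unclass(as_contour(drawing))[, 1:2]
  pts <- cbind((p[, 1] + 0.5) * canvas, (0.5 - p[, 2]) * canvas)
  jit <- model$closure_jitter
  last <- pts[1, ] + if (jit > 0) jit * c(cos(0.7), sin(0.7)) else c(0, 0)
  rbind(pts, last)
}
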