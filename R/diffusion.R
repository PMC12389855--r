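# Forward diffusion for the pressure frame and the refined mask.
#
# Both streams share one noise schedule but draw independent per-step noise:
# the mask trajectory mirrors the pressure trajectory step for step, which is
# what keeps the two synchronized during reverse denoising.

#' Create a linear-decay noise schedule
#'
#' Per-step retention factors `alpha[t]` interpolate linearly from
#' `alpha_start` (t = 1) down to `alpha_end` (t = D), so the signal share
#' shrinks and the injected-noise share grows monotonically along the chain.
#'
#' Two parameterisations of the forward step are supported. In
#' `"variance_preserving"` (default, the standard DDPM form) a step is
#' `sqrt(alpha[t]) * x + sqrt(1 - alpha[t]) * eps`; in `"linear_retention"` it is
#' `alpha[t] * x + sqrt(1 - alpha[t]) * eps`, i.e. the retention factor is not
#' square-rooted.
#'
#' @param D number of diffusion steps (positive integer).
#' @param alpha_start retention factor at t = 1, in (0, 1].
#' @param alpha_end retention factor at t = D, with 0 < alpha_end <= alpha_start.
#' @param mode `"variance_preserving"` or `"linear_retention"`.
#' @return an object of class `noise_schedule` with fields `D`, `alphas`, `mode`.
#' @export
#' @examples
#' s <- make_schedule(3, 1.0, 0.5)
#' s$alphas # 1.00 0.75 0.50
make_schedule <- function(D, alpha_start = 0.999, alpha_end = 0.95,
                          mode = c("variance_preserving", "linear_retention")) {
  mode <- match.arg(mode)
  if (length(D) != 1 || is.na(D) || D < 1 || D != round(D)) {
    stop_("D must be a positive integer (got %s)", format(D))
  }
  if (!(alpha_end > 0 && alpha_end <= alpha_start && alpha_start <= 1)) {
    stop_("need 0 < alpha_end <= alpha_start <= 1 (got %g, %g)",
          alpha_start, alpha_end)
  }
  alphas <- if (D == 1) alpha_start else
    alpha_start + (alpha_end - alpha_start) * (seq_len(D) - 1) / (D - 1)
  structure(list(D = as.integer(D), alphas = alphas, mode = mode),
            class = "noise_schedule")
}

step_scale <- function(sched, t) {
  a <- sched$alphas[t]
  if (sched$mode == "variance_preserving") sqrt(a) else a
}

#' Signal retention and marginal variance of the forward chain
#'
#' Closed-form moments of `x_t` given `x_0`, obtained by unrolling the forward
#' recursion: the mean is `scale_t * x_0` with `scale_t` the product of the
#' per-step retention factors, and the variance accumulates each step's
#' injected noise attenuated by all later retentions.
#'
#' @param sched a [make_schedule()] object.
#' @param t step, 0..D (vectorised).
#' @return numeric vector.
#' @export
diffusion_signal_scale <- function(sched, t) {
  s <- cumprod(vapply(seq_len(sched$D), function(i) step_scale(sched, i),
                      numeric(1)))
  c(1, s)[t + 1L]
}

#' @rdname diffusion_signal_scale
#' @export
diffusion_marginal_var <- function(sched, t) {
  v <- 0
  out <- numeric(sched$D + 1)
  for (i in seq_len(sched$D)) {
    v <- step_scale(sched, i)^2 * v + (1 - sched$alphas[i])
    out[i + 1] <- v
  }
  out[t + 1L]
}

#' One forward diffusion step
#'
#' Mixes the previous grid with fresh standard-normal noise according to the
#' schedule's retention factor at step `t`.
#'
#' @param x_prev numeric matrix, signal at step t - 1.
#' @param t step index in 1..D.
#' @param sched a [make_schedule()] object.
#' @param rng_seed integer seed for the noise draw.
#' @return matrix of the same shape.
#' @export
forward_step <- function(x_prev, t, sched, rng_seed) {
  if (length(t) != 1 || t < 1 || t > sched$D) {
    stop_("step t must lie in 1..%d (got %s)", sched$D, format(t))
  }
  eps <- with_seed(rng_seed, matrix(rnorm(length(x_prev)), nrow(x_prev)))
  step_scale(sched, t) * x_prev + sqrt(1 - sched$alphas[t]) * eps
}

#' Full forward diffusion trajectory
#'
#' Applies [forward_step()] iteratively with independent per-step noise whose
#' seeds are derived from `rng_seed` by counter hashing.
#'
#' @param x0 numeric matrix at step 0.
#' @param sched a [make_schedule()] object.
#' @param rng_seed integer root seed.
#' @return list of D + 1 matrices; element `[[t + 1]]` is the signal at step t.
#' @export
forward_trajectory <- function(x0, sched, rng_seed) {
  stopifnot(all(is.finite(x0)))
  out <- vector("list", sched$D + 1)
  out[[1]] <- x0
  for (t in seq_len(sched$D)) {
    out[[t + 1]] <- forward_step(out[[t]], t, sched,
                                 derive_seed(rng_seed, "step", t))
  }
  out
}

#' Sample the forward marginal at one step directly
#'
#' Equivalent in distribution to running the chain to step t; used for
#' per-step training pairs without materialising whole trajectories.
#'
#' @inheritParams forward_trajectory
#' @param t target step, 0..D.
#' @return matrix of the same shape as `x0`.
#' @export
diffuse_to <- function(x0, t, sched, rng_seed) {
  if (t == 0) return(x0)
  eps <- with_seed(rng_seed, matrix(rnorm(length(x0)), nrow(x0)))
  diffusion_signal_scale(sched, t) * x0 +
    sqrt(diffusion_marginal_var(sched, t)) * eps
}
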