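#' Explicit dwell-time model with a geometric tail
#'
#' Dwell times (number of current samples emitted per k-mer) are modelled by
#' a discretized log-logistic distribution up to a maximum explicit duration
#' `Dbar`, beyond which the probability decays geometrically with factor
#' `gamma` (realized in the state space as a self-loop on the top duration
#' state). The discrete head is obtained by half-integer CDF differences of
#' the continuous log-logistic: `eta(d) = F(d + 1/2) - F(d - 1/2)` for
#' `d < Dbar`, with `F(x) = 1 / (1 + (x/a)^-b)`. The mass `eta(Dbar)` is set
#' so that the total, head plus tail `eta(Dbar) / (1 - gamma)`, is exactly 1.
#'
#' With `gamma = "mean-matched"` the tail factor is chosen so that the mean
#' of the discrete model equals the mean of the continuous log-logistic
#' (`a * (pi/b) / sin(pi/b)`, finite for `b > 1`), giving a representative
#' mean dwell time.
#'
#' @param a log-logistic scale parameter (> 0, in samples); the mean dwell is
#'   proportional to `a`.
#' @param b log-logistic shape parameter (> 0).
#' @param Dbar maximum explicit duration (positive integer).
#' @param gamma tail factor in `[0, 1)`, or `"mean-matched"` (default).
#' @param scale per-read positive multiplier applied to `a` (default 1); see
#'   [estimate_duration_scale()].
#' @return An object of class `duration_model`: list with `eta` (length
#'   `Dbar`), `gamma`, `Dbar`, `a`, `b`, `scale`, `gamma_mode` and
#'   `eta_entry` (the normalized duration distribution used on entry into a
#'   new k-mer, whose top bucket absorbs the whole tail).
#' @examples
#' dm <- duration_model(a = 6, b = 2.5, Dbar = 10)
#' sum(dm$eta[-dm$Dbar]) + dm$eta[dm$Dbar] / (1 - dm$gamma)  # 1
#' @export
duration_model <- function(a, b, Dbar, gamma = "mean-matched", scale = 1) {
  if (a <= 0 || b <= 0) stopf("'a' and 'b' must be positive")
  if (scale <= 0) stopf("'scale' must be positive")
  Dbar <- as.integer(Dbar)
  if (is.na(Dbar) || Dbar < 1L) stopf("'Dbar' must be a positive integer")
  gamma_mode <- if (identical(gamma, "mean-matched")) "mean-matched" else "fixed"
  if (gamma_mode == "fixed") {
    gamma <- as.numeric(gamma)
    if (is.na(gamma) || gamma < 0 || gamma >= 1) {
      stopf("'gamma' must lie in [0, 1) or be \"mean-matched\"")
    }
  }
  ae <- a * scale
  cdf <- function(x) 1 / (1 + (x / ae)^(-b))
  head <- if (Dbar > 1L) {
    d <- seq_len(Dbar - 1L)
    cdf(d + 0.5) - cdf(pmax(d - 0.5, 0))
  } else numeric(0)
  leftover <- 1 - sum(head) # total tail mass eta(Dbar)/(1 - gamma)
  if (leftover <= 0) stopf("'Dbar' too large for these parameters")
  if (gamma_mode == "mean-matched") {
    if (b <= 1) stopf("mean-matched tail requires b > 1 (finite mean)")
    mu <- ae * (pi / b) / sin(pi / b)
    s1 <- if (Dbar > 1L) sum(seq_len(Dbar - 1L) * head) else 0
    t <- max((mu - s1 - leftover * Dbar) / leftover, 0)
    gamma <- t / (1 + t)
  }
  eta <- c(head, (1 - gamma) * leftover)
  structure(
    list(eta = eta, gamma = gamma, Dbar = Dbar, a = a, b = b, scale = scale,
         gamma_mode = gamma_mode,
         eta_entry = c(head, leftover)),
    class = "duration_model"
  )
}

#' Probability mass function of the dwell-time model
#'
#' Includes the analytic geometric tail: `eta(Dbar + m) = gamma^m * eta(Dbar)`.
#'
#' @param dm a [duration_model()].
#' @param d vector of positive integer durations.
#' @return vector of probabilities.
#' @export
duration_pmf <- function(dm, d) {
  d <- as.integer(d)
  p <- numeric(length(d))
  if (any(d < 1L)) stopf("durations must be >= 1")
  head <- d < dm$Dbar
  p[head] <- dm$eta[d[head]]
  p[!head] <- dm$eta[dm$Dbar] * dm$gamma^(d[!head] - dm$Dbar)
  p
}

#' Mean of the dwell-time model (tail included)
#' @param dm a [duration_model()].
#' @return the mean dwell in samples.
#' @export
duration_mean <- function(dm) {
  Dbar <- dm$Dbar
  s1 <- if (Dbar > 1L) sum(seq_len(Dbar - 1L) * dm$eta[-Dbar]) else 0
  tail_mass <- dm$eta[Dbar] / (1 - dm$gamma)
  s1 + tail_mass * (Dbar + dm$gamma / (1 - dm$gamma))
}

#' Rescale a dwell-time model for one read
#'
#' Applies a per-read multiplicative factor to the log-logistic scale
#' parameter, the single knob used for read-specific dwell adjustment (reads
#' taken later in a run dwell longer as ATP depletes). A mean-matched tail is
#' re-matched under the new scale.
#'
#' @param dm a [duration_model()].
#' @param scale positive multiplier (replaces the current one).
#' @return a new `duration_model`.
#' @export
rescale_duration <- function(dm, scale) {
  g <- if (dm$gamma_mode == "mean-matched") "mean-matched" else dm$gamma
  duration_model(dm$a, dm$b, dm$Dbar, gamma = g, scale = scale)
}

#' @export
print.duration_model <- function(x, ...) {
  cat(sprintf(
    "dwell-time model: log-logistic(a = %.3g, b = %.3g) x %.3g, Dbar = %d, gamma = %.4f (%s)\n",
    x$a, x$b, x$scale, x$Dbar, x$gamma, x$gamma_mode))
  cat(sprintf("  mean dwell = %.3f samples\n", duration_mean(x)))
  invisible(x)
}

#' Estimate the mean dwell time of a read from its raw signal
#'
#' Counts samples where the signal jumps by more than
#' `change_threshold * mad(signal)` between consecutive samples (level shifts
#' at k-mer boundaries) and returns `N / max(count, 1)` clipped to `clip`.
#' Dividing the result by the mean of a base [duration_model()] gives the
#' per-read `scale` for [rescale_duration()].
#'
#' @param signal numeric vector of current samples (length >= 2).
#' @param change_threshold jump threshold in units of the read's median
#'   absolute deviation (default 0.2; raw signals are normalized so k-mer
#'   level gaps are of order the signal MAD while in-level noise is much
#'   smaller).
#' @param clip length-2 numeric range the estimate is clipped to.
#' @return estimated mean dwell in samples.
#' @export
estimate_duration_scale <- function(signal, change_threshold = 0.1,
                                    clip = c(1, 50)) {
  if (length(signal) < 2L) stopf("signal must have at least 2 samples")
  if (!all(is.finite(signal))) stopf("signal contains non-finite samples")
  thr <- change_threshold * stats::mad(signal)
  count <- sum(abs(diff(signal)) > thr)
  est <- length(signal) / max(count, 1)
  min(max(est, clip[1]), clip[2])
}
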