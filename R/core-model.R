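#' @include AllClasses.R AllGenerics.R
NULL

# continuous-time system matrices of the time-normalised point-mass model:
# state (r_x, v_x, r_y, v_y), input (u_x, u_y) scaled by 1/m.
.tipmA <- function() {
  matrix(c(0, 1, 0, 0,
           0, 0, 0, 0,
           0, 0, 0, 1,
           0, 0, 0, 0), 4, 4, byrow = TRUE)
}
.tipmB <- function(mass) {
  matrix(c(0, 0,
           1 / mass, 0,
           0, 0,
           0, 1 / mass), 4, 2, byrow = TRUE)
}
.gravityOffset <- function(params) c(0, 0, 0, -params@g * params@Tbar^2)

#' Zero-phase low-pass filter for position trajectories
#'
#' Applies a 6th-order Butterworth low-pass (cut-off 2 Hz by default, the
#' standard choice for slow whole-body movement) forwards and backwards
#' (`filtfilt`), so the output is zero-phase and the length is preserved.
#'
#' @param series numeric vector, the raw position samples (m).
#' @param sampleRate sampling rate (Hz); must exceed twice the cut-off.
#' @param cutoff cut-off frequency (Hz), default 2.
#' @param order filter order, default 6.
#' @return The filtered series, same length as the input.
#' @export
filterPositions <- function(series, sampleRate, cutoff = 2, order = 6) {
  minLen <- 4 * order
  if (length(series) < minLen)
    stop("filterPositions: series has ", length(series),
         " samples but at least ", minLen, " are required for filter warm-up")
  if (sampleRate <= 2 * cutoff)
    stop("filterPositions: sample rate must exceed twice the cut-off")
  bf <- signal::butter(order, cutoff / (sampleRate / 2), type = "low")
  .filtfiltSettled(bf$b, bf$a, series)
}

# forward-backward filtering with odd-reflection padding and settled initial
# conditions, so constants and slow trends pass without edge transients
.filtfiltSettled <- function(b, a, x) {
  n <- length(a)
  # initial filter state producing a settled response to a unit step
  A <- diag(n - 1) -
    cbind(-a[2:n], rbind(diag(1, n - 2), rep(0, n - 2)))
  zi <- solve(A, b[2:n] - b[1] * a[2:n])
  nfact <- 3 * (n - 1)
  L <- length(x)
  pad <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[L] - x[(L - 1):(L - nfact)])
  df2t <- function(xx) { # direct-form II transposed with state zi * xx[1]
    z <- zi * xx[1]
    y <- numeric(length(xx))
    for (i in seq_along(xx)) {
      y[i] <- b[1] * xx[i] + z[1]
      z <- c(z[-1], 0) + b[-1] * xx[i] - a[-1] * y[i]
    }
    y
  }
  out <- rev(df2t(rev(df2t(pad))))
  out[(nfact + 1):(nfact + L)]
}

#' Numerical differentiation on a uniform grid
#'
#' Central differences in the interior, one-sided differences at the ends;
#' exact for quadratics in the interior.
#'
#' @param series numeric vector.
#' @param dt sample spacing (scalar), or the full time vector (uniformity is
#'   then checked).
#' @return The derivative series, same length as the input.
#' @export
differentiate <- function(series, dt) {
  n <- length(series)
  if (n < 3) stop("differentiate: need at least 3 samples")
  if (length(dt) > 1) {
    steps <- diff(dt)
    if (any(abs(steps - steps[1]) > 1e-9 * max(abs(steps))))
      stop("differentiate: time grid is not uniform")
    dt <- steps[1]
  }
  if (dt <= 0) stop("differentiate: dt must be positive")
  out <- numeric(n)
  out[2:(n - 1)] <- (series[3:n] - series[1:(n - 2)]) / (2 * dt)
  out[1] <- (series[2] - series[1]) / dt
  out[n] <- (series[n] - series[n - 1]) / dt
  out
}

#' Normalise a trial onto the dimensionless grid
#'
#' Maps a trial from its own time axis \eqn{\tau \in [0, T]} to
#' \eqn{t = \tau / T \in [0, 1]}: velocities are multiplied by T and
#' accelerations and forces by T^2 (the chain-rule factors of the time
#' rescaling), and every channel is resampled by linear interpolation onto
#' `nSteps + 1` evenly spaced grid points. The validity mask marks samples
#' inside the perturbation window, which are excluded from controller
#' fitting.
#'
#' @param trial a [StsTrial-class].
#' @param nSteps number of grid intervals (default 200, matching the basin's
#'   time step of 0.005).
#' @return A [NormalizedTrial-class].
#' @export
normalizeTrial <- function(trial, nSteps = 200) {
  stopifnot(is(trial, "StsTrial"))
  T <- trial@duration
  tg <- seq(0, 1, length.out = nSteps + 1)
  src <- trial@time / T
  rs <- function(v) stats::approx(src, v, xout = tg, rule = 2)$y
  pos <- cbind(rs(trial@pos[, 1]), rs(trial@pos[, 2]))
  vel <- cbind(rs(trial@vel[, 1]), rs(trial@vel[, 2])) * T
  acc <- cbind(rs(trial@acc[, 1]), rs(trial@acc[, 2])) * T^2
  dst <- cbind(rs(trial@dist[, 1]), rs(trial@dist[, 2])) * T^2
  toe <- if (length(trial@toeX) > 0) rs(trial@toeX) else numeric(0)
  mask <- rep(TRUE, nSteps + 1)
  if (length(trial@pertWindow) == 2)
    mask <- !(tg >= trial@pertWindow[1] & tg <= trial@pertWindow[2])
  new("NormalizedTrial",
      tGrid = tg,
      state = cbind(pos[, 1], vel[, 1], pos[, 2], vel[, 2]),
      acc = acc, dist = dst,
      input = matrix(numeric(0), 0, 2),
      validMask = mask, toeX = toe,
      duration = T, strategy = trial@strategy, trialType = trial@trialType,
      pertWindow = trial@pertWindow, label = trial@label,
      subjectMass = trial@subjectMass)
}

#' Undo the time normalisation of a trial
#'
#' Exact inverse of the scaling in [normalizeTrial()] evaluated on the
#' normalised grid (the resampling itself is not inverted).
#'
#' @param trial a [NormalizedTrial-class].
#' @return A [StsTrial-class] on the grid \eqn{\tau = T t}.
#' @export
denormalizeTrial <- function(trial) {
  stopifnot(is(trial, "NormalizedTrial"))
  T <- trial@duration
  new("StsTrial",
      time = trial@tGrid * T,
      pos = trial@state[, c(1, 3)],
      vel = trial@state[, c(2, 4)] / T,
      acc = trial@acc / T^2,
      dist = trial@dist / T^2,
      toeX = trial@toeX,
      duration = T, strategy = trial@strategy, trialType = trial@trialType,
      pertWindow = trial@pertWindow, label = trial@label,
      subjectMass = trial@subjectMass)
}

#' Recover control inputs by inverse dynamics
#'
#' Rearranging the time-normalised point-mass dynamics gives the input that
#' must have acted at each sample:
#' \eqn{u_x = m a_x - d_x}, \eqn{u_y = m (a_y + g T^2) - d_y},
#' with accelerations and cable forces in normalised units and T the trial's
#' own duration. Samples inside the perturbation window remain flagged
#' invalid via the trial's mask and are excluded from downstream fitting.
#'
#' @param trial a [NormalizedTrial-class].
#' @param params a [TipmParams-class] (supplies the mass).
#' @return The trial with its `input` slot filled (201 x 2 matrix).
#' @export
inverseDynamics <- function(trial, params) {
  stopifnot(is(trial, "NormalizedTrial"), is(params, "TipmParams"))
  if (nrow(trial@acc) == 0)
    stop("inverseDynamics: trial has no acceleration channels")
  m <- params@mass
  T <- trial@duration
  u <- cbind(m * trial@acc[, 1] - trial@dist[, 1],
             m * (trial@acc[, 2] + params@g * T^2) - trial@dist[, 2])
  trial@input <- u
  validObject(trial)
  trial
}

#' Simulate the closed- or open-loop model forward
#'
#' Fixed-step 4th-order Runge-Kutta integration of
#' \deqn{\dot x = (v_x,\; (u_x + d_x)/m,\; v_y,\; (u_y + d_y)/m - g \bar T^2)}
#' on the normalised time axis.
#'
#' @param x0 initial 4-vector state.
#' @param inputLaw either a function `(t, x) -> c(u_x, u_y)` or an
#'   `(nSteps + 1) x 2` matrix of inputs on the uniform grid (linearly
#'   interpolated between grid points).
#' @param d disturbance: `NULL`, a function `(t) -> c(d_x, d_y)`, or a
#'   matrix like `inputLaw`.
#' @param params a [TipmParams-class].
#' @param tSpan integration interval, default `c(0, 1)`.
#' @param nSteps number of RK4 steps (default 200).
#' @return An `(nSteps + 1) x 4` state trajectory with the time grid in
#'   attribute `"time"`.
#' @export
simulateForward <- function(x0, inputLaw, d = NULL, params,
                            tSpan = c(0, 1), nSteps = 200) {
  stopifnot(length(x0) == 4, tSpan[1] < tSpan[2])
  tg <- seq(tSpan[1], tSpan[2], length.out = nSteps + 1)
  h <- (tSpan[2] - tSpan[1]) / nSteps
  ufun <- .asSignal(inputLaw, tg, "inputLaw")
  dfun <- if (is.null(d)) function(t) c(0, 0) else .asSignal(d, tg, "d")
  m <- params@mass
  gT2 <- params@g * params@Tbar^2
  deriv <- function(t, x) {
    u <- ufun(t, x)
    w <- dfun(t)
    c(x[2], (u[1] + w[1]) / m, x[4], (u[2] + w[2]) / m - gT2)
  }
  out <- matrix(NA_real_, nSteps + 1, 4)
  out[1, ] <- x0
  x <- as.numeric(x0)
  for (k in seq_len(nSteps)) {
    t <- tg[k]
    k1 <- deriv(t, x)
    k2 <- deriv(t + h / 2, x + h / 2 * k1)
    k3 <- deriv(t + h / 2, x + h / 2 * k2)
    k4 <- deriv(t + h, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!all(is.finite(x)))
      stop("simulateForward: non-finite state at step ", k,
           " (t = ", format(tg[k + 1]), ")")
    out[k + 1, ] <- x
  }
  attr(out, "time") <- tg
  out
}

# turn a matrix-of-samples or function into a callable signal
.asSignal <- function(sig, tg, what) {
  if (is.function(sig)) {
    if (length(formals(sig)) >= 2) return(sig)
    return(function(t, x) sig(t))
  }
  sig <- as.matrix(sig)
  if (nrow(sig) != length(tg))
    stop(what, ": expected ", length(tg), " samples, got ", nrow(sig))
  function(t, x) {
    s <- (t - tg[1]) / (tg[length(tg)] - tg[1]) * (length(tg) - 1)
    i <- min(max(floor(s), 0), length(tg) - 2)
    w <- s - i
    (1 - w) * sig[i + 1, ] + w * sig[i + 2, ]
  }
}

# linear interpolation helpers for per-grid-point quantities
.interpRows <- function(M, tGrid, t) {
  s <- (t - tGrid[1]) / (tGrid[length(tGrid)] - tGrid[1]) * (length(tGrid) - 1)
  i <- min(max(floor(s), 0), length(tGrid) - 2)
  w <- s - i
  (1 - w) * M[i + 1, ] + w * M[i + 2, ]
}
.interpGain <- function(K, tGrid, t) {
  s <- (t - tGrid[1]) / (tGrid[length(tGrid)] - tGrid[1]) * (length(tGrid) - 1)
  i <- min(max(floor(s), 0), length(tGrid) - 2)
  w <- s - i
  (1 - w) * K[, , i + 1] + w * K[, , i + 2]
}
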