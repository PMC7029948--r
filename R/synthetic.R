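#' @include AllClasses.R AllGenerics.R core-model.R evaluation.R
NULL

#' Configuration of the synthetic Sit-to-Stand experiment
#'
#' The generator emulates a perturbative Sit-to-Stand protocol for one
#' subject: per strategy, a block of nominal trials, a block of foot-shift
#' trials (initial anterior-posterior offsets in 0.05-m increments), and a
#' block of cable-pull trials at three peak force levels, half pulling
#' forwards and half backwards, with onset drawn around mid-motion. Each
#' trial is forward-simulated under a ground-truth bounded controller
#' (nominal input plus smooth trial-to-trial input noise plus PD recovery
#' feedback, all saturated inside a fixed band), so the total input always
#' stays within known bounds; failures arise mechanistically when the
#' recovery demanded by a pull exceeds the band for long enough.
#'
#' @slot seed integer; fixes all randomness.
#' @slot mass subject mass (kg).
#' @slot durations 3 x 2 matrix (rows natural, momentum_transfer,
#'   quasi_static; columns mean, sd) of trial durations (s).
#' @slot nNominal,nFootshift,nPerturbed trial counts per strategy.
#' @slot pertAccel peak cable-pull accelerations (m s^-2; force = mass x
#'   accel) for the low/medium/high levels.
#' @slot pertOnset mean and sd of perturbation onset (fraction of the trial).
#' @slot pertDuration cable-pull pulse duration (s).
#' @slot boundAccel half-width of the ground-truth input band, expressed as
#'   accelerations (m s^-2) in x and y.
#' @slot fbGains PD recovery gains per unit mass, `c(kp, kd)` (s^-2, s^-1).
#' @slot noiseRho range of the per-trial input-noise amplitude as a fraction
#'   of the band half-width.
#' @slot seatPos,standPos centre-of-mass start/end positions (m), origin at
#'   the initial ball of the foot.
#' @slot accBump per-strategy horizontal acceleration-shaping amplitude (m),
#'   giving the characteristic ordering quasi-static < natural <
#'   momentum-transfer of horizontal acceleration extremes.
#' @slot abortDev horizontal deviation from the nominal path (m) at which
#'   the strategy is abandoned (forward: step; backward: sit).
#' @slot stepLimit absolute anterior centre-of-mass position (m) that also
#'   triggers a step.
#' @slot endFraction fraction of the full seat-to-stand path covered by the
#'   defined trial segment (default 0.9): segmentation ends before quiet
#'   standing, so end-of-trial velocities are still positive.
#' @slot sampleRate output sampling rate (Hz).
#' @export
setClass("SyntheticConfig",
  representation(seed = "numeric", mass = "numeric", durations = "matrix",
                 nNominal = "numeric", nFootshift = "numeric",
                 nPerturbed = "numeric", pertAccel = "numeric",
                 pertOnset = "numeric", pertDuration = "numeric",
                 boundAccel = "numeric", fbGains = "numeric",
                 noiseRho = "numeric", seatPos = "numeric",
                 standPos = "numeric", accBump = "numeric",
                 abortDev = "numeric", stepLimit = "numeric",
                 endFraction = "numeric", sampleRate = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(c(object@nNominal, object@nFootshift, object@nPerturbed) < 0))
      msg <- c(msg, "trial counts must be nonnegative")
    if (any(object@durations <= 0 & col(object@durations) == 1))
      msg <- c(msg, "mean durations must be positive")
    if (object@mass <= 0) msg <- c(msg, "mass must be positive")
    if (length(object@pertAccel) != 3)
      msg <- c(msg, "three perturbation levels are expected")
    if (length(msg)) msg else TRUE
  }
)

#' @param seed,mass,durations,nNominal,nFootshift,nPerturbed,pertAccel
#'   see the class slots.
#' @param pertOnset,pertDuration,boundAccel,fbGains,noiseRho,seatPos,standPos
#'   see the class slots.
#' @param accBump,abortDev,stepLimit,sampleRate see the class slots.
#' @return A [SyntheticConfig-class].
#' @rdname SyntheticConfig-class
#' @export
syntheticConfig <- function(seed = 42,
                            mass = 65.4,
                            durations = NULL,
                            nNominal = 5, nFootshift = 6, nPerturbed = 18,
                            pertAccel = c(1.6, 2.4, 2.8),
                            pertOnset = c(0.50, 0.10),
                            pertDuration = 0.150,
                            boundAccel = c(0.45, 0.90),
                            fbGains = c(16, 8),
                            noiseRho = c(0.15, 1.05),
                            seatPos = c(-0.25, 0.58),
                            standPos = c(0.00, 0.95),
                            accBump = c(natural = 0.020,
                                        momentum_transfer = 0.050,
                                        quasi_static = 0.005),
                            abortDev = 0.06,
                            stepLimit = 0.12,
                            endFraction = 0.9,
                            sampleRate = 120) {
  if (is.null(durations)) {
    durations <- matrix(c(1.25, 0.23,
                          1.13, 0.21,
                          2.23, 0.89), 3, 2, byrow = TRUE,
                        dimnames = list(.STRATEGIES, c("mean", "sd")))
  }
  new("SyntheticConfig", seed = seed, mass = mass, durations = durations,
      nNominal = nNominal, nFootshift = nFootshift, nPerturbed = nPerturbed,
      pertAccel = pertAccel, pertOnset = pertOnset,
      pertDuration = pertDuration, boundAccel = boundAccel,
      fbGains = fbGains, noiseRho = noiseRho, seatPos = seatPos,
      standPos = standPos, accBump = accBump, abortDev = abortDev,
      stepLimit = stepLimit, endFraction = endFraction,
      sampleRate = sampleRate)
}

# minimum-jerk interpolant and its derivatives on t in [0, 1]
.minJerk <- function(t) {
  list(s = 10 * t^3 - 15 * t^4 + 6 * t^5,
       sd = 30 * t^2 - 60 * t^3 + 30 * t^4,
       sdd = 60 * t - 180 * t^2 + 120 * t^3)
}
# smooth zero-endpoint acceleration-shaping bump and derivatives
.bump <- function(t) {
  g <- 4 * t * (1 - t); gd <- 4 - 8 * t; gdd <- -8
  s <- sin(2 * pi * t); c2 <- 2 * pi * cos(2 * pi * t)
  list(w = s * g,
       wd = c2 * g + s * gd,
       wdd = -(2 * pi)^2 * s * g + 2 * c2 * gd + s * gdd)
}

#' Nominal centre-of-mass path for a strategy
#'
#' A minimum-jerk seat-to-stand path with a strategy-dependent horizontal
#' shaping term, so that the horizontal acceleration envelopes order as
#' quasi-static < natural < momentum-transfer. Endpoints match the
#' configured seat/stand positions exactly, with zero endpoint velocities.
#'
#' @param config a [SyntheticConfig-class].
#' @param strategy strategy label.
#' @param duration trial duration (s); defaults to the strategy mean.
#' @param footOffset initial anterior-posterior offset of the path start (m).
#' @param tau sample times (s); defaults to the configured sampling rate.
#' @return A list with `time`, `pos`, `vel`, `acc` (n x 2 matrices, lab
#'   units).
#' @export
makeNominalPath <- function(config, strategy, duration = NULL,
                            footOffset = 0, tau = NULL) {
  stopifnot(strategy %in% .STRATEGIES)
  if (is.null(duration)) duration <- config@durations[strategy, 1]
  if (is.null(tau))
    tau <- seq(0, duration,
               length.out = ceiling(duration * config@sampleRate) + 1)
  fn <- .pathFns(config, strategy, duration, footOffset)
  list(time = tau, pos = fn$r(tau), vel = fn$v(tau), acc = fn$a(tau))
}

# closed-form path functions of real time tau (vectorised)
.pathFns <- function(config, strategy, duration, footOffset = 0) {
  p0 <- config@seatPos + c(footOffset, 0)
  p1 <- config@standPos
  d <- p1 - p0
  A <- unname(config@accBump[strategy])
  T <- duration
  r <- function(tau) {
    t <- tau / T; mj <- .minJerk(t); b <- .bump(t)
    cbind(p0[1] + d[1] * mj$s + A * b$w, p0[2] + d[2] * mj$s)
  }
  v <- function(tau) {
    t <- tau / T; mj <- .minJerk(t); b <- .bump(t)
    cbind(d[1] * mj$sd + A * b$wd, d[2] * mj$sd) / T
  }
  a <- function(tau) {
    t <- tau / T; mj <- .minJerk(t); b <- .bump(t)
    cbind(d[1] * mj$sdd + A * b$wdd, d[2] * mj$sdd) / T^2
  }
  list(r = r, v = v, a = a)
}

# smooth unit-amplitude noise profile over [0, T] with an endpoint-vanishing
# envelope (trials converge tightly to standing, keeping the target set small)
.noiseProfile <- function(T, tau) {
  a <- stats::runif(3) / (1:3)
  ph <- stats::runif(3, 0, 2 * pi)
  s <- rowSums(vapply(1:3, function(h) a[h] * sin(2 * pi * h * tau / T + ph[h]),
                      numeric(length(tau))))
  m <- max(abs(s))
  if (m > 0) s <- s / m
  s * sin(pi * tau / T)^2
}

# simulate one trial under the ground-truth saturated controller.
# All signals (nominal path, noise, pulse) are precomputed on the half-step
# grid, which the RK4 stage times land on exactly.
# Returns lab-unit series at the output rate plus ground-truth bookkeeping.
.simulateTrial <- function(config, strategy, duration, footOffset = 0,
                           pulse = NULL) {
  m <- config@mass; g <- 9.81
  W <- config@boundAccel * m              # band half-width in N
  kp <- config@fbGains[1]; kd <- config@fbGains[2]
  Tfull <- duration / config@endFraction   # trial ends before quiet standing
  fn <- .pathFns(config, strategy, Tfull, footOffset)
  fine <- 480
  # detection runs past the defined trial end, but stops before the nominal
  # path fully decelerates (where zero nominal velocity would make the
  # sit rule fire on settling noise)
  horizon <- min(1.25 * duration, 0.95 * Tfull)
  nF <- ceiling(horizon * fine)
  h <- horizon / nF
  tauF <- seq(0, by = h, length.out = nF + 1)
  tauH <- seq(0, by = h / 2, length.out = 2 * nF + 1)  # half-step grid
  onPath <- tauH <= Tfull
  tcl <- pmin(tauH, Tfull)
  RN <- fn$r(tcl); VN <- fn$v(tcl); AN <- fn$a(tcl)
  if (any(!onPath)) { # settle with a slight upward drift, approaching from below
    drift <- c(0.005, 0.010)
    idx <- which(!onPath)
    RN[idx, ] <- RN[idx, ] + (tauH[idx] - Tfull) %o% drift
    VN[idx, ] <- matrix(drift, length(idx), 2, byrow = TRUE)
    AN[idx, ] <- 0
  }
  rhoX <- stats::runif(1, config@noiseRho[1], config@noiseRho[2])
  rhoY <- stats::runif(1, config@noiseRho[1], config@noiseRho[2])
  ETA <- cbind(W[1] * pmin(pmax(rhoX * .noiseProfile(duration, pmin(tauH, duration)),
                                -1), 1),
               W[2] * pmin(pmax(rhoY * .noiseProfile(duration, pmin(tauH, duration)),
                                -1), 1))
  DX <- numeric(2 * nF + 1)
  if (!is.null(pulse)) {
    dtp <- tauH - pulse$onset
    act <- dtp >= 0 & dtp <= config@pertDuration
    DX[act] <- pulse$dir * pulse$accel * m *
      sin(pi * dtp[act] / config@pertDuration)
  }
  mode <- "track"; modeAt <- NA_real_
  uLaw <- function(j, r, v) { # j indexes the half-step grid
    if (mode == "track") {
      uNom <- m * (AN[j, ] + c(0, g))
      fb <- m * (kp * (RN[j, ] - r) + kd * (VN[j, ] - v)) + ETA[j, ]
      uNom + pmin(pmax(fb, -W), W)
    } else if (mode == "step") {
      tgt <- RN[j, ] + c(0.30, -0.10)
      m * (6 * (tgt - r) + 5 * (c(0.2, 0) - v)) + c(0, 0.95 * m * g)
    } else { # sit
      tgt <- config@seatPos + c(-0.05, 0)
      m * (6 * (tgt - r) - 5 * v) + c(0, 0.92 * m * g)
    }
  }
  deriv <- function(j, x) {
    u <- uLaw(j, x[c(1, 3)], x[c(2, 4)])
    c(x[2], (u[1] + DX[j]) / m, x[4], u[2] / m - g)
  }
  X <- matrix(NA_real_, nF + 1, 4)
  Uap <- matrix(NA_real_, nF + 1, 2)
  x <- c(config@seatPos[1] + footOffset, 0, config@seatPos[2], 0)
  X[1, ] <- x
  for (k in seq_len(nF + 1)) {
    j <- 2 * k - 1
    Uap[k, ] <- uLaw(j, x[c(1, 3)], x[c(2, 4)])
    if (k > nF) break
    k1 <- deriv(j, x)
    k2 <- deriv(j + 1, x + h / 2 * k1)
    k3 <- deriv(j + 1, x + h / 2 * k2)
    k4 <- deriv(j + 2, x + h * k3)
    x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    X[k + 1, ] <- x
    if (mode == "track") {
      dev <- x[1] - RN[j + 2, 1]
      if (dev > config@abortDev || x[1] > config@stepLimit) {
        mode <- "step"; modeAt <- tauF[k + 1]
      } else if (dev < -config@abortDev) {
        mode <- "sit"; modeAt <- tauF[k + 1]
      }
    }
  }
  # toe proxy: flat until (reaction-delayed) step onset, then a fast swing
  toe <- numeric(nF + 1)
  if (mode == "step") {
    t0 <- modeAt + 0.03
    toe <- pmin(pmax(tauF - t0, 0) * 1.0, 0.25)
  }
  Dap <- cbind(DX[seq(1, 2 * nF + 1, by = 2)], 0)
  acc <- cbind((Uap[, 1] + Dap[, 1]) / m, Uap[, 2] / m - g)
  # labels from the evaluation rules on the extended series
  stepT <- detectStep(toe, tauF / duration)
  sitT <- detectSit(X[, 2], X[, 4], tauF / duration,
                    persist = max(3, round(0.025 * fine)))
  outc <- assignFailure(stepT, sitT)
  keep <- which(tauF <= duration + 1e-12)
  thin <- keep[seq(1, length(keep), by = round(fine / config@sampleRate))]
  jthin <- 2 * thin - 1
  list(time = tauF[thin], pos = X[thin, c(1, 3), drop = FALSE],
       vel = X[thin, c(2, 4), drop = FALSE],
       acc = acc[thin, , drop = FALSE],
       dist = Dap[thin, , drop = FALSE],
       toe = toe[thin],
       label = outc$label, tF = outc$tF, mode = mode,
       uApplied = Uap[thin, , drop = FALSE],
       uNominal = m * (fn$a(pmin(tauF[thin], Tfull)) +
                         matrix(c(0, g), length(thin), 2, byrow = TRUE)),
       W = W)
}

#' Generate a labelled synthetic Sit-to-Stand dataset
#'
#' Produces, per strategy, nominal, foot-shift and cable-pull trials
#' simulated under the ground-truth bounded controller, with outcome labels
#' assigned by the step/sit detection rules applied to the simulated series
#' (detection runs 25\% past the defined trial end, so failures with onset
#' after t = 1 keep their unsuccessful label with the onset clamped, as in
#' the evaluation protocol). Fully reproducible from the seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param strategies which strategies to generate (default all three).
#' @return A list with `trials` (named list of [StsTrial-class]) and `truth`
#'   (per-trial ground-truth records: applied inputs, band half-widths,
#'   failure mode bookkeeping).
#' @export
generateDataset <- function(config, strategies = .STRATEGIES) {
  set.seed(config@seed)
  trials <- list()
  truth <- list(config = config, trials = list())
  for (strategy in strategies) {
    mu <- config@durations[strategy, 1]
    sdv <- config@durations[strategy, 2]
    drawT <- function() min(max(stats::rnorm(1, mu, sdv), 0.55 * mu), 1.8 * mu)
    specs <- list()
    for (i in seq_len(config@nNominal))
      specs[[length(specs) + 1]] <- list(type = "nominal", offset = 0,
                                         pulse = NULL)
    offsets <- c(-0.15, -0.10, -0.05, 0.05, 0.10, 0.15)
    for (i in seq_len(config@nFootshift))
      specs[[length(specs) + 1]] <- list(type = "foot_shift",
                                         offset = offsets[(i - 1) %% 6 + 1],
                                         pulse = NULL)
    nPert <- config@nPerturbed
    levels <- rep(seq_along(config@pertAccel), length.out = nPert)
    dirs <- rep(c(1, 1, 1, -1, -1, -1), length.out = nPert)
    ord <- sample(nPert)
    for (i in seq_len(nPert)) {
      lev <- levels[ord[i]]; dir <- dirs[ord[i]]
      specs[[length(specs) + 1]] <- list(type = "perturbed", offset = 0,
                                         pulse = list(level = lev, dir = dir,
                                                      accel = config@pertAccel[lev]))
    }
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      T <- drawT()
      pulse <- sp$pulse
      if (!is.null(pulse)) {
        onsetFrac <- min(max(stats::rnorm(1, config@pertOnset[1],
                                          config@pertOnset[2]), 0.10), 0.85)
        pulse$onset <- onsetFrac * T
      }
      sim <- .simulateTrial(config, strategy, T, footOffset = sp$offset,
                            pulse = pulse)
      win <- if (!is.null(pulse))
        c(pulse$onset / T, min((pulse$onset + config@pertDuration) / T, 1))
      else numeric(0)
      id <- sprintf("%s_%s_%02d", strategy, sp$type, i)
      trials[[id]] <- new("StsTrial",
        time = sim$time, pos = sim$pos, vel = sim$vel, acc = sim$acc,
        dist = sim$dist, toeX = sim$toe, duration = T,
        strategy = strategy, trialType = sp$type, pertWindow = win,
        label = sim$label, subjectMass = config@mass)
      truth$trials[[id]] <- list(strategy = strategy, type = sp$type,
                                 level = if (!is.null(pulse)) pulse$level else NA,
                                 dir = if (!is.null(pulse)) pulse$dir else NA,
                                 onset = if (!is.null(pulse)) pulse$onset else NA,
                                 label = sim$label, tF = sim$tF,
                                 mode = sim$mode, duration = T,
                                 uApplied = sim$uApplied,
                                 uNominal = sim$uNominal, W = sim$W)
    }
  }
  list(trials = trials, truth = truth)
}

#' Ground-truth input band of a nominal trial, normalised units
#'
#' The generating controller draws its bounded component from
#' \eqn{u_{nom}(\tau) \pm W \min(1, \rho_{max} \sin^2(\pi \tau/T))}
#' (lab units): the saturation band is \eqn{\pm W}, but the trial-to-trial
#' input noise carries an endpoint-vanishing envelope, so this is the band
#' the controller actually exercises on nominal trials. The helper returns
#' it on the normalised grid, scaled by \eqn{T^2} like any normalised
#' force.
#'
#' @param config a [SyntheticConfig-class].
#' @param strategy strategy label.
#' @param duration trial duration (s); defaults to the strategy mean.
#' @param tGrid normalised grid (default 201 points).
#' @return A list with `lb` and `ub` (n x 2 matrices, normalised units).
#' @export
groundTruthBounds <- function(config, strategy, duration = NULL,
                              tGrid = seq(0, 1, length.out = 201)) {
  if (is.null(duration)) duration <- config@durations[strategy, 1]
  fn <- .pathFns(config, strategy, duration / config@endFraction)
  m <- config@mass
  uNom <- m * (fn$a(tGrid * duration) +
                 matrix(c(0, 9.81), length(tGrid), 2, byrow = TRUE))
  env <- pmin(1, config@noiseRho[2] * sin(pi * tGrid)^2)
  W <- outer(env, config@boundAccel * m)
  list(lb = (uNom - W) * duration^2, ub = (uNom + W) * duration^2)
}

#' Write a dataset to per-trial CSV + JSON sidecar files
#'
#' One CSV per trial (columns tau, r_x, v_x, a_x, r_y, v_y, a_y, d_x, d_y,
#' toe_x) and a JSON sidecar with the metadata, in the package's interchange
#' format.
#'
#' @param trials named list of [StsTrial-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of CSV paths written.
#' @export
exportDataset <- function(trials, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(trials), function(id) {
    writeTrial(trials[[id]], file.path(dir, paste0(id, ".csv")))
  }, character(1))
  invisible(paths)
}
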