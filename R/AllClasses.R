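#' @import methods
NULL

.STRATEGIES <- c("natural", "momentum_transfer", "quasi_static")
.TRIAL_TYPES <- c("nominal", "foot_shift", "perturbed")
.LABELS <- c("success", "step", "sit", "unknown")

#' Zonotope set representation
#'
#' A zonotope is the centrally symmetric polytope
#' \eqn{Z = \{c + G\beta : \|\beta\|_\infty \le 1\}} given by a centre
#' \eqn{c \in R^n} and a generator matrix \eqn{G \in R^{n \times p}} whose
#' columns are the generators. Zonotopes are closed under linear maps and
#' Minkowski sums, which is what makes them the workhorse set representation
#' for reachability analysis. A zonotope with zero generator columns is the
#' singleton \eqn{\{c\}}.
#'
#' @slot center numeric vector, the centre \eqn{c}.
#' @slot generators numeric matrix with \code{length(center)} rows; each
#'   column is one generator.
#'
#' @seealso [Zonotope()], [containsPoint()], [linearMap()], [minkowskiSum()],
#'   [reduceOrder()], [dilate()], [fitZonotope()]
#' @export
setClass("Zonotope",
  representation(center = "numeric", generators = "matrix"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@generators) != length(object@center))
      msg <- c(msg, "generator matrix must have one row per state dimension")
    if (!all(is.finite(object@center)) ||
        (length(object@generators) > 0 && !all(is.finite(object@generators))))
      msg <- c(msg, "all entries must be finite")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a Zonotope
#'
#' @param center numeric centre vector.
#' @param generators numeric matrix of generators (columns); `NULL` for the
#'   singleton \eqn{\{c\}}.
#' @return A [Zonotope-class] object.
#' @examples
#' Zonotope(c(0, 0), diag(2))          # unit square
#' Zonotope(c(1, 2))                   # singleton
#' @export
Zonotope <- function(center, generators = NULL) {
  center <- as.numeric(center)
  if (is.null(generators))
    generators <- matrix(numeric(0), nrow = length(center), ncol = 0)
  generators <- as.matrix(generators)
  storage.mode(generators) <- "double"
  new("Zonotope", center = center, generators = generators)
}

#' Telescoping inverted pendulum model parameters
#'
#' The model is a sagittal-plane point mass at the body centre of mass with
#' horizontal and vertical force inputs. `mass` is the subject mass, `g` the
#' gravitational acceleration, and `Tbar` the canonical trial duration for a
#' strategy: the time-normalised basin dynamics need a single time scale for
#' the gravity term, and the mean duration of the strategy's nominal trials
#' is used for this.
#'
#' @slot mass subject mass (kg).
#' @slot g gravitational acceleration (m s^-2, fixed at 9.81).
#' @slot Tbar canonical trial duration for the strategy (s).
#' @export
setClass("TipmParams",
  representation(mass = "numeric", g = "numeric", Tbar = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@mass) != 1 || object@mass <= 0)
      msg <- c(msg, "mass must be a positive scalar")
    if (length(object@g) != 1 || !isTRUE(all.equal(object@g, 9.81)))
      msg <- c(msg, "g is fixed at 9.81 m s^-2")
    if (length(object@Tbar) != 1 || object@Tbar <= 0)
      msg <- c(msg, "Tbar must be a positive scalar")
    if (length(msg)) msg else TRUE
  }
)

#' @param mass subject mass (kg).
#' @param Tbar canonical trial duration (s).
#' @param g gravitational acceleration; fixed at 9.81 m s^-2.
#' @return A [TipmParams-class] object.
#' @rdname TipmParams-class
#' @export
tipmParams <- function(mass, Tbar, g = 9.81) {
  new("TipmParams", mass = as.numeric(mass), g = as.numeric(g),
      Tbar = as.numeric(Tbar))
}

#' One Sit-to-Stand trial in laboratory units
#'
#' Centre-of-mass kinematics of a single trial on its own time grid
#' \eqn{\tau \in [0, T]} (seconds), with the origin at the initial position of
#' the ball of the foot. Positions are metres, velocities m/s, accelerations
#' m/s^2, cable-pull forces newtons. The perturbation window is stored as a
#' fraction of the trial (\%STS / 100) and must be present exactly for
#' perturbed trials.
#'
#' @slot time sample times (s), uniform grid on \eqn{[0, T]}.
#' @slot pos,vel,acc n x 2 matrices, columns (x = anterior-posterior,
#'   y = vertical).
#' @slot dist n x 2 matrix of cable-pull force components (N).
#' @slot toeX anterior-posterior toe positions (m), or length 0 if absent.
#' @slot duration trial duration T (s).
#' @slot strategy one of `"natural"`, `"momentum_transfer"`, `"quasi_static"`.
#' @slot trialType one of `"nominal"`, `"foot_shift"`, `"perturbed"`.
#' @slot pertWindow numeric(2) perturbation onset/offset as a fraction of the
#'   trial, or numeric(0).
#' @slot label observed outcome, one of `"success"`, `"step"`, `"sit"`,
#'   `"unknown"`.
#' @slot subjectMass subject mass (kg).
#' @export
setClass("StsTrial",
  representation(time = "numeric", pos = "matrix", vel = "matrix",
                 acc = "matrix", dist = "matrix", toeX = "numeric",
                 duration = "numeric", strategy = "character",
                 trialType = "character", pertWindow = "numeric",
                 label = "character", subjectMass = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@time)
    for (s in c("pos", "vel", "acc", "dist")) {
      m <- slot(object, s)
      if (nrow(m) != n || ncol(m) != 2)
        msg <- c(msg, sprintf("'%s' must be a %d x 2 matrix", s, n))
    }
    if (length(object@toeX) > 0 && length(object@toeX) != n)
      msg <- c(msg, "'toeX' must match the time grid length")
    if (object@duration <= 0) msg <- c(msg, "duration must be positive")
    if (!object@strategy %in% .STRATEGIES)
      msg <- c(msg, "unknown strategy label")
    if (!object@trialType %in% .TRIAL_TYPES)
      msg <- c(msg, "unknown trial type")
    if (!object@label %in% .LABELS) msg <- c(msg, "unknown outcome label")
    has_win <- length(object@pertWindow) == 2
    if (object@trialType == "perturbed" && !has_win)
      msg <- c(msg, "perturbed trials must carry a perturbation window")
    if (object@trialType != "perturbed" && length(object@pertWindow) != 0)
      msg <- c(msg, "only perturbed trials may carry a perturbation window")
    if (length(msg)) msg else TRUE
  }
)

#' A trial on the dimensionless Sit-to-Stand grid
#'
#' Trajectories resampled onto the common grid \eqn{t \in [0, 1]} (201 points,
#' 200 intervals) with time-normalised units: velocities are multiplied by the
#' trial duration T and accelerations/forces by T^2, so that trials of
#' different durations are directly comparable. The 4-vector model state is
#' \eqn{x = (r_x, v_x, r_y, v_y)}. `validMask` is `FALSE` exactly on samples
#' inside the perturbation window; those samples are excluded from controller
#' fitting because the recorded inputs there reflect the cable pull, not the
#' subject's strategy.
#'
#' @slot tGrid the 201-point grid on \eqn{[0, 1]}.
#' @slot state 201 x 4 matrix \eqn{(r_x, v_x, r_y, v_y)}.
#' @slot acc,dist,input 201 x 2 matrices in normalised units; `input` has 0
#'   rows until inverse dynamics has been run.
#' @slot validMask logical 201-vector.
#' @slot toeX resampled toe positions (m, unscaled), or length 0.
#' @slot duration,strategy,trialType,pertWindow,label,subjectMass provenance
#'   copied from the source trial.
#' @export
setClass("NormalizedTrial",
  representation(tGrid = "numeric", state = "matrix", acc = "matrix",
                 dist = "matrix", input = "matrix", validMask = "logical",
                 toeX = "numeric", duration = "numeric",
                 strategy = "character", trialType = "character",
                 pertWindow = "numeric", label = "character",
                 subjectMass = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- length(object@tGrid)
    if (n < 2 || abs(object@tGrid[1]) > 1e-12 || abs(object@tGrid[n] - 1) > 1e-12)
      msg <- c(msg, "tGrid must run from 0 to 1")
    if (nrow(object@state) != n || ncol(object@state) != 4)
      msg <- c(msg, "state must be n x 4")
    if (nrow(object@acc) != n || nrow(object@dist) != n)
      msg <- c(msg, "acc/dist must be defined on the grid")
    if (nrow(object@input) > 0 && nrow(object@input) != n)
      msg <- c(msg, "input, when present, must be defined on the grid")
    if (length(object@validMask) != n)
      msg <- c(msg, "validMask must be defined on the grid")
    if (length(msg)) msg else TRUE
  }
)

#' Training data for controller fitting
#'
#' All successful trials of one subject and strategy, with inputs recovered by
#' inverse dynamics and perturbation windows masked out.
#'
#' @slot trials list of [NormalizedTrial-class] with `input` filled.
#' @slot strategy the common strategy label.
#' @slot params the [TipmParams-class] used for inverse dynamics.
#' @export
setClass("TrainingSet",
  representation(trials = "list", strategy = "character",
                 params = "TipmParams"),
  validity = function(object) {
    msg <- character()
    if (length(object@trials) < 1) msg <- c(msg, "at least one trial required")
    strat <- vapply(object@trials, function(tr) tr@strategy, character(1))
    if (length(unique(strat)) > 1)
      msg <- c(msg, "all trials must share one strategy")
    lab <- vapply(object@trials, function(tr) tr@label, character(1))
    if (!all(lab == "success"))
      msg <- c(msg, "training trials must all be labelled success")
    if (length(msg)) msg else TRUE
  }
)

#' Average nominal trajectory and its open-loop input
#'
#' The pointwise mean of the nominal trials' normalised states, together with
#' the open-loop input recovered from the mean trajectory by inverse dynamics
#' (recomputed from the averaged accelerations, not averaged inputs).
#'
#' @slot tGrid the 201-point grid.
#' @slot xBar 201 x 4 mean state trajectory.
#' @slot uOl 201 x 2 open-loop input.
#' @export
setClass("AvgNominal",
  representation(tGrid = "numeric", xBar = "matrix", uOl = "matrix"))

#' Virtual parent of the three controller models
#'
#' @slot tGrid 201-point grid on which gains are stored; they are linearly
#'   interpolated for off-grid queries.
#' @slot strategy the strategy the controller was fit for.
#' @export
setClass("StsController",
  representation("VIRTUAL", tGrid = "numeric", strategy = "character"))

#' Finite-horizon LQR tracking controller
#'
#' \eqn{u(t, x) = u_{ol}(t) - K(t) (x - \bar x(t))}: linear feedback about the
#' average nominal trajectory, with gains from a finite-horizon discrete-time
#' Riccati recursion under diagonal weights Q (states) and R (inputs) chosen
#' to best reproduce the observed inputs.
#'
#' @slot Q 4 x 4 diagonal state weight, Q[1,1] fixed at 1.
#' @slot R 2 x 2 diagonal input weight.
#' @slot K 2 x 4 x 201 gain array.
#' @slot avg the [AvgNominal-class] tracked by the controller.
#' @export
setClass("LqrController",
  contains = "StsController",
  representation(Q = "matrix", R = "matrix", K = "array",
                 avg = "AvgNominal"),
  validity = function(object) {
    msg <- character()
    if (any(object@Q[upper.tri(object@Q)] != 0) ||
        any(object@R[upper.tri(object@R)] != 0))
      msg <- c(msg, "Q and R must be diagonal")
    if (abs(object@Q[1, 1] - 1) > 1e-12) msg <- c(msg, "Q[1,1] must equal 1")
    if (length(msg)) msg else TRUE
  }
)

#' Feed-forward plus feedback controller
#'
#' \eqn{u(t, x) = ff(t) - K(t) x}: a per-time-step linear least-squares fit of
#' observed inputs against observed states.
#'
#' @slot ff 201 x 2 feed-forward term.
#' @slot K 2 x 4 x 201 feedback gain array.
#' @export
setClass("FfFbController",
  contains = "StsController",
  representation(ff = "matrix", K = "array"))

#' Set-valued input-bounds controller
#'
#' Models the input as a bounded component plus shared linear feedback:
#' \eqn{u(t,x) \in [b_{lb}(t) - K(t) x,\; b_{ub}(t) - K(t) x]}. The bounds
#' are fitted per time step by a constrained least-squares quadratic program
#' that forces every observed training input inside the band.
#'
#' @slot bLb,bUb 201 x 2 lower/upper bounded components.
#' @slot K 2 x 4 x 201 shared feedback gain array.
#' @export
setClass("InputBoundsController",
  contains = "StsController",
  representation(bLb = "matrix", bUb = "matrix", K = "array"),
  validity = function(object) {
    if (any(object@bLb > object@bUb + 1e-9))
      "lower bounded component exceeds upper at some time step" else TRUE
  }
)

#' Stability Basin: time-indexed backward reachable sets
#'
#' The Stability Basin is the set of model states, indexed over the motion
#' from 0 to 100\% STS, from which the closed-loop model still arrives at the
#' target set at t = 1. It is stored as one zonotope per grid point
#' (time step 0.005, i.e. 200 propagation steps), computed by flowing the
#' target set backwards under the negated closed-loop dynamics.
#'
#' @slot slices list of 201 [Zonotope-class] slices at t = 0, 0.005, ..., 1.
#' @slot target the target set \eqn{X_T} (equal to the slice at t = 1 for an
#'   undilated basin).
#' @slot controllerType one of `"lqr"`, `"fffb"`, `"input_bounds"`, `"naive"`.
#' @slot params the [TipmParams-class] of the closed-loop dynamics.
#' @slot dt normalised time step (default 0.005).
#' @slot maxGenerators generator cap applied during propagation (default 800).
#' @slot dilation cumulative generator dilation factor applied to the slices
#'   (1 for an undilated basin).
#' @export
setClass("StabilityBasin",
  representation(slices = "list", target = "Zonotope",
                 controllerType = "character", params = "TipmParams",
                 dt = "numeric", maxGenerators = "numeric",
                 dilation = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- round(1 / object@dt)
    if (length(object@slices) != n + 1)
      msg <- c(msg, sprintf("expected %d slices for dt = %g", n + 1, object@dt))
    dims <- vapply(object@slices, function(z) length(z@center), integer(1))
    if (any(dims != 4)) msg <- c(msg, "every slice must be 4-dimensional")
    ng <- vapply(object@slices, function(z) ncol(z@generators), integer(1))
    if (any(ng > object@maxGenerators))
      msg <- c(msg, "generator count exceeds the configured cap")
    if (length(msg)) msg else TRUE
  }
)

#' Per-trial classification outcome
#'
#' @slot trialId identifier of the classified trial.
#' @slot observed observed outcome label.
#' @slot tF failure-onset time (normalised), or NA for successful trials.
#' @slot predicted `"success"` or `"failure"`.
#' @slot firstExit normalised time of the first basin exit, or NA.
#' @slot betaTrace per-slice containment coefficients \eqn{\beta_{max}} over
#'   the admissible window (named by slice time).
#' @export
setClass("TrialOutcome",
  representation(trialId = "character", observed = "character",
                 tF = "numeric", predicted = "character",
                 firstExit = "numeric", betaTrace = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@observed != "success" && is.na(object@tF))
      msg <- c(msg, "unsuccessful trials must carry a failure-onset time")
    if (object@predicted == "failure" && is.na(object@firstExit))
      msg <- c(msg, "predicted failures must carry a first-exit time")
    if (length(msg)) msg else TRUE
  }
)

# ---- show methods ----------------------------------------------------------

setMethod("show", "Zonotope", function(object) {
  cat(sprintf("Zonotope in R^%d with %d generators\n",
              length(object@center), ncol(object@generators)))
  cat("  center:", format(object@center, digits = 4), "\n")
})

setMethod("show", "TipmParams", function(object) {
  cat(sprintf("TIPM parameters: mass %.2f kg, g %.2f m/s^2, Tbar %.3f s\n",
              object@mass, object@g, object@Tbar))
})

setMethod("show", "StsTrial", function(object) {
  cat(sprintf("StsTrial: %s/%s, T = %.3f s, %d samples, label %s\n",
              object@strategy, object@trialType, object@duration,
              length(object@time), object@label))
})

setMethod("show", "NormalizedTrial", function(object) {
  cat(sprintf(
    "NormalizedTrial: %s/%s, T = %.3f s, %d grid points, label %s%s\n",
    object@strategy, object@trialType, object@duration,
    length(object@tGrid), object@label,
    if (nrow(object@input) > 0) ", inputs computed" else ""))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d successful %s trials\n",
              length(object@trials), object@strategy))
})

setMethod("show", "StabilityBasin", function(object) {
  ng <- vapply(object@slices, function(z) ncol(z@generators), integer(1))
  cat(sprintf(
    "StabilityBasin (%s): %d slices, dt = %g, generators %d..%d%s\n",
    object@controllerType, length(object@slices) - 1, object@dt,
    min(ng), max(ng),
    if (object@dilation != 1) sprintf(", dilated %.2fx", object@dilation) else ""))
})

setMethod("show", "TrialOutcome", function(object) {
  cat(sprintf("TrialOutcome %s: observed %s%s, predicted %s%s\n",
              object@trialId, object@observed,
              if (!is.na(object@tF)) sprintf(" (t_f = %.3f)", object@tF) else "",
              object@predicted,
              if (!is.na(object@firstExit))
                sprintf(" (first exit %.3f)", object@firstExit) else ""))
})
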