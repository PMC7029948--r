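#' @include AllClasses.R AllGenerics.R zonotope.R controllers.R
NULL

#' Build the target set from successful final states
#'
#' The target set \eqn{X_T} is the oriented-box zonotope (4 generators,
#' expanded 5\%) around the states at t = 1 of all successful trials of a
#' strategy. It encodes "states observed to lead to standing", not quiet
#' standing itself.
#'
#' @param train a [TrainingSet-class] (or list of [NormalizedTrial-class]).
#' @param expansion generator expansion (default 0.05).
#' @return A [Zonotope-class].
#' @export
buildTargetSet <- function(train, expansion = 0.05) {
  trials <- if (is(train, "TrainingSet")) train@trials else train
  if (length(trials) == 0) stop("buildTargetSet: no successful trials")
  finals <- t(vapply(trials, function(tr) tr@state[nrow(tr@state), ],
                     numeric(4)))
  fitZonotope(finals, nGenerators = 4, expansion = expansion)
}

#' One backward propagation step of a basin slice
#'
#' With the closed-loop matrix frozen at the step midpoint, the slice at
#' time t - dt is the image of the slice at t under the reversed flow:
#' \deqn{Z^{(t-\Delta t)} = e^{-A_{cl}\Delta t} Z^{(t)} \oplus \Gamma (-W),
#'   \quad \Gamma = \sum_{k=0}^{10} (-A_{cl})^k \frac{\Delta t^{k+1}}{(k+1)!}}
#' where W is the affine input-effect set of the controller. The result is
#' order-reduced to the generator cap. For the single-valued controllers W is
#' a singleton and the propagation is exact up to the matrix-exponential
#' truncation; for the input-bounds controller W is the image of the input
#' box and each step adds its two generators.
#'
#' @param Z the slice at time `t` (a [Zonotope-class]).
#' @param ctrl a controller object.
#' @param t the time of slice `Z` (the step computes the slice at `t - dt`).
#' @param dt time step (default 0.005).
#' @param params a [TipmParams-class].
#' @param maxGenerators generator cap (default 800).
#' @param taylorOrder truncation order of the input-effect integral
#'   (default 10; the remainder at dt = 0.005 is far below solver
#'   tolerances).
#' @return The slice at `t - dt`.
#' @export
backwardReachStep <- function(Z, ctrl, t, dt = 0.005, params,
                              maxGenerators = 800, taylorOrder = 10) {
  if (t - dt < -1e-9)
    stop("backwardReachStep: step would leave [0, 1] (t = ", t, ")")
  cl <- closedLoopSystem(ctrl, max(t - dt / 2, 0), params)
  nA <- -cl$Acl
  if (!all(is.finite(nA)))
    stop("backwardReachStep: non-finite closed-loop matrix at t = ", t)
  Phi <- expm::expm(nA * dt)
  Gam <- diag(4) * dt
  term <- diag(4)
  for (k in seq_len(taylorOrder)) {
    term <- term %*% nA
    Gam <- Gam + term * dt^(k + 1) / factorial(k + 1)
  }
  Znext <- minkowskiSum(linearMap(Phi, Z), linearMap(-Gam, cl$W))
  reduceOrder(Znext, maxGenerators)
}

#' Compute a Stability Basin by backward reachability
#'
#' Treats the target set as an initial set and flows it backwards in time
#' under the negated closed-loop dynamics, producing one zonotope per grid
#' point: 200 propagation steps of length 0.005 from t = 1 down to t = 0.
#'
#' @param ctrl a controller object ([LqrController-class],
#'   [FfFbController-class] or [InputBoundsController-class]).
#' @param target the target set \eqn{X_T} (a [Zonotope-class]).
#' @param params a [TipmParams-class].
#' @param dt time step (default 0.005).
#' @param maxGenerators generator cap (default 800).
#' @return A [StabilityBasin-class].
#' @export
computeBasin <- function(ctrl, target, params, dt = 0.005,
                         maxGenerators = 800) {
  n <- round(1 / dt)
  if (abs(n * dt - 1) > 1e-9) stop("computeBasin: dt must divide 1 evenly")
  slices <- vector("list", n + 1)
  slices[[n + 1]] <- target
  for (k in n:1) {
    slices[[k]] <- tryCatch(
      backwardReachStep(slices[[k + 1]], ctrl, t = k * dt, dt = dt,
                        params = params, maxGenerators = maxGenerators),
      error = function(e)
        stop("computeBasin: step ", k, " failed: ", conditionMessage(e)))
  }
  type <- switch(class(ctrl),
                 LqrController = "lqr",
                 FfFbController = "fffb",
                 InputBoundsController = "input_bounds",
                 class(ctrl))
  new("StabilityBasin", slices = slices, target = target,
      controllerType = type, params = params, dt = dt,
      maxGenerators = maxGenerators, dilation = 1)
}

#' Naive stability estimate from observed states alone
#'
#' Draws an oriented-box zonotope (4 generators, 5\% expansion, the same
#' construction as the target set) around the observed successful states at
#' every grid point. No dynamics or controller model is used.
#'
#' @param train a [TrainingSet-class] or list of [NormalizedTrial-class].
#' @param params a [TipmParams-class].
#' @param dt time step (default 0.005; the trials' grid must match).
#' @param expansion generator expansion (default 0.05).
#' @return A [StabilityBasin-class] with `controllerType = "naive"`.
#' @export
computeNaiveBasin <- function(train, params, dt = 0.005, expansion = 0.05) {
  trials <- if (is(train, "TrainingSet")) train@trials else train
  if (length(trials) == 0) stop("computeNaiveBasin: no trials")
  n <- round(1 / dt)
  nT <- length(trials[[1]]@tGrid)
  if (nT != n + 1)
    stop("computeNaiveBasin: trials are on a ", nT - 1,
         "-interval grid but dt = ", dt)
  slices <- vector("list", n + 1)
  for (k in seq_len(n + 1)) {
    pts <- t(vapply(trials, function(tr) tr@state[k, ], numeric(4)))
    slices[[k]] <- fitZonotope(pts, nGenerators = 4, expansion = expansion)
  }
  new("StabilityBasin", slices = slices, target = slices[[n + 1]],
      controllerType = "naive", params = params, dt = dt,
      maxGenerators = 800, dilation = 1)
}

#' @describeIn dilate dilate every slice of a basin (generators scaled,
#'   centres fixed); the stored target set is kept as-is and the cumulative
#'   factor is recorded in the `dilation` slot.
setMethod("dilate", signature("StabilityBasin", "numeric"),
  function(Z, factor) {
    if (factor <= 0) stop("dilate: factor must be positive")
    Z@slices <- lapply(Z@slices, dilate, factor = factor)
    Z@dilation <- Z@dilation * factor
    Z
  })

#' Dilate a Stability Basin
#'
#' Multiplies every slice's generators by `factor` (centres unchanged).
#' Containment is monotone in the factor: any point inside a slice stays
#' inside the dilated slice.
#'
#' @param basin a [StabilityBasin-class].
#' @param factor positive scale factor (e.g. 1.05 or 1.25).
#' @return The dilated basin.
#' @export
dilateBasin <- function(basin, factor) dilate(basin, factor)

setMethod("basinSlices", "StabilityBasin", function(basin) basin@slices)

setMethod("basinSlice", signature("StabilityBasin", "numeric"),
  function(basin, t) {
    if (t < -1e-9 || t > 1 + 1e-9) stop("basinSlice: t outside [0, 1]")
    basin@slices[[min(max(round(t / basin@dt), 0), round(1 / basin@dt)) + 1]]
  })

#' Export 2-D projections of basin slices for plotting
#'
#' Writes per-slice interval hulls of the horizontal \eqn{(r_x, v_x)} and
#' vertical \eqn{(r_y, v_y)} projections to CSV, one row per slice.
#'
#' @param basin a [StabilityBasin-class].
#' @param path output CSV path.
#' @return Invisibly, the data frame written.
#' @export
exportBasinProjections <- function(basin, path) {
  rows <- lapply(seq_along(basin@slices), function(k) {
    z <- basin@slices[[k]]
    halves <- rowSums(abs(z@generators))
    data.frame(t = (k - 1) * basin@dt,
               rx_lo = z@center[1] - halves[1], rx_hi = z@center[1] + halves[1],
               vx_lo = z@center[2] - halves[2], vx_hi = z@center[2] + halves[2],
               ry_lo = z@center[3] - halves[3], ry_hi = z@center[3] + halves[3],
               vy_lo = z@center[4] - halves[4], vy_hi = z@center[4] + halves[4])
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
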