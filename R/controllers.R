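#' @include AllClasses.R AllGenerics.R core-model.R
NULL

#' Assemble controller training data from successful trials
#'
#' Training data are the successful trials (nominal, foot-shift and
#' successful perturbed) of one subject and strategy. Inputs are recovered by
#' [inverseDynamics()]; samples inside a perturbation window stay masked out
#' through each trial's validity mask, because the recorded accelerations
#' there reflect the cable pull rather than the subject's own control.
#'
#' @param trials list of [NormalizedTrial-class], all labelled `"success"`
#'   and sharing one strategy.
#' @param params a [TipmParams-class].
#' @return A [TrainingSet-class].
#' @export
buildTrainingSet <- function(trials, params) {
  if (length(trials) == 0) stop("buildTrainingSet: no trials supplied")
  lab <- vapply(trials, function(tr) tr@label, character(1))
  if (!all(lab == "success"))
    stop("buildTrainingSet: trials must all be labelled success (got: ",
         paste(unique(lab[lab != "success"]), collapse = ", "), ")")
  strat <- unique(vapply(trials, function(tr) tr@strategy, character(1)))
  if (length(strat) > 1)
    stop("buildTrainingSet: mixed strategies: ", paste(strat, collapse = ", "))
  trials <- lapply(trials, inverseDynamics, params = params)
  new("TrainingSet", trials = trials, strategy = strat, params = params)
}

#' Average nominal trajectory and open-loop input
#'
#' The mean of the nominal trials' normalised state trajectories, with the
#' open-loop input recomputed from the averaged accelerations by inverse
#' dynamics (using the canonical duration `Tbar`, the time scale of the basin
#' dynamics) rather than by averaging per-trial inputs.
#'
#' @param nominalTrials list of [NormalizedTrial-class] nominal trials.
#' @param params a [TipmParams-class].
#' @return An [AvgNominal-class].
#' @export
averageNominal <- function(nominalTrials, params) {
  if (length(nominalTrials) == 0)
    stop("averageNominal: no nominal trials supplied")
  tg <- nominalTrials[[1]]@tGrid
  xBar <- Reduce(`+`, lapply(nominalTrials, function(tr) tr@state)) /
    length(nominalTrials)
  aBar <- Reduce(`+`, lapply(nominalTrials, function(tr) tr@acc)) /
    length(nominalTrials)
  m <- params@mass
  uOl <- cbind(m * aBar[, 1],
               m * (aBar[, 2] + params@g * params@Tbar^2))
  new("AvgNominal", tGrid = tg, xBar = xBar, uOl = uOl)
}

# zero-order-hold discretisation of the (A, B) pair; A is nilpotent
# (A^2 = 0) so the matrix exponentials are exact two-term sums.
.zohPair <- function(mass, dt) {
  A <- .tipmA()
  B <- .tipmB(mass)
  Ad <- diag(4) + A * dt
  Bd <- (diag(4) * dt + A * dt^2 / 2) %*% B
  list(Ad = Ad, Bd = Bd)
}

#' Finite-horizon LQR gains about the nominal trajectory
#'
#' Runs the discrete-time finite-horizon Riccati recursion backwards from the
#' terminal cost P(1) = Q on the zero-order-hold discretisation of the
#' point-mass dynamics, returning the feedback gain at every time step.
#'
#' @param Q 4 x 4 diagonal positive-definite state weight.
#' @param R 2 x 2 diagonal positive-definite input weight.
#' @param params a [TipmParams-class].
#' @param dt time step (default 0.005).
#' @param horizon length of the horizon in normalised time (default 1).
#' @return A 2 x 4 x (nSteps + 1) gain array; the final slice duplicates the
#'   last computed gain so the array covers the full closed grid.
#' @export
fitLqrGains <- function(Q, R, params, dt = 0.005, horizon = 1) {
  .checkDiagPd(Q, "Q"); .checkDiagPd(R, "R")
  zoh <- .zohPair(params@mass, dt)
  n <- round(horizon / dt)
  K <- .lqr_riccati(zoh$Ad, zoh$Bd, Q, R, n)
  Kfull <- array(NA_real_, c(2, 4, n + 1))
  Kfull[, , seq_len(n)] <- K
  Kfull[, , n + 1] <- K[, , n]
  Kfull
}

.checkDiagPd <- function(M, name) {
  if (any(M[row(M) != col(M)] != 0) || any(diag(M) <= 0))
    stop(name, " must be diagonal positive definite")
}

# pack a training set into the dense arrays the C++ objective expects
.trainingArrays <- function(train) {
  trials <- train@trials
  nT <- length(trials[[1]]@tGrid)
  ntr <- length(trials)
  X <- array(NA_real_, c(4, nT, ntr))
  U <- array(NA_real_, c(2, nT, ntr))
  mask <- matrix(0L, nT, ntr)
  for (i in seq_len(ntr)) {
    X[, , i] <- t(trials[[i]]@state)
    U[, , i] <- t(trials[[i]]@input)
    mask[, i] <- as.integer(trials[[i]]@validMask)
  }
  list(X = X, U = U, mask = mask, nT = nT, ntr = ntr)
}

#' Choose LQR weights that best explain the observed inputs
#'
#' Minimises the summed squared error between the LQR law
#' \eqn{u_{ol}(t) - K(t)(x_i(t) - \bar x(t))} and the inverse-dynamics inputs
#' of the training trials, over diagonal weights constrained to
#' \eqn{Q_{11} = 1}, \eqn{Q_{22}, Q_{33}, Q_{44} \in [0.1, 100]},
#' \eqn{R_{11} \in [10^{-5}, 10^{-2}]} and \eqn{R_{22} \in [10^{-6}, 10^{-1}]}
#' (the boxes restrict relative state/input costs). The error integral is
#' approximated with 200 time steps. The optimiser is deterministic: a
#' 5-point-per-axis log-space grid followed by Nelder-Mead refinement clipped
#' to the box.
#'
#' @param train a [TrainingSet-class].
#' @param avg an [AvgNominal-class].
#' @param params a [TipmParams-class].
#' @param dt time step (default 0.005).
#' @param gridPoints grid resolution per axis (default 5).
#' @return A list with `Q`, `R`, and the objective `value` attained.
#' @export
optimizeLqrWeights <- function(train, avg, params, dt = 0.005,
                               gridPoints = 5) {
  arr <- .trainingArrays(train)
  m <- params@mass
  nT <- arr$nT
  Xbar <- t(avg@xBar)
  Uol <- t(avg@uOl)
  Ux <- matrix(arr$U[1, , ], nT, arr$ntr)
  Uy <- matrix(arr$U[2, , ], nT, arr$ntr)
  # the dynamics, diagonal weights and squared-error objective decouple into
  # the horizontal and vertical 2x2 subsystems, so the box search factorises
  objx <- function(lq) # lq = log10(Q22, R11)
    .lqr_axis_obj(dt, m, 1, 10^lq[1], 10^lq[2],
                  Xbar[1:2, , drop = FALSE], Uol[1, ],
                  arr$X[1:2, , , drop = FALSE], Ux, arr$mask)
  objy <- function(lq) # lq = log10(Q33, Q44, R22)
    .lqr_axis_obj(dt, m, 10^lq[1], 10^lq[2], 10^lq[3],
                  Xbar[3:4, , drop = FALSE], Uol[2, ],
                  arr$X[3:4, , , drop = FALSE], Uy, arr$mask)
  gq <- seq(log10(0.1), log10(100), length.out = gridPoints)
  grx <- as.matrix(expand.grid(gq, seq(-5, -2, length.out = gridPoints)))
  gry <- as.matrix(expand.grid(gq, gq, seq(-6, -1, length.out = gridPoints)))
  bestx <- grx[which.min(apply(grx, 1, objx)), ]
  besty <- gry[which.min(apply(gry, 1, objy)), ]
  lo <- c(log10(0.1), -5, log10(0.1), log10(0.1), -6)
  hi <- c(log10(100), -2, log10(100), log10(100), -1)
  f <- function(p) {
    p <- pmin(pmax(p, lo), hi)
    objx(p[1:2]) + objy(p[3:5])
  }
  ref <- stats::optim(c(bestx, besty), f, method = "Nelder-Mead",
                      control = list(maxit = 600, reltol = 1e-12))
  sol <- pmin(pmax(ref$par, lo), hi)
  list(Q = diag(c(1, 10^sol[1], 10^sol[3], 10^sol[4])),
       R = diag(10^c(sol[2], sol[5])), value = ref$value)
}

#' Fit the LQR controller model
#'
#' Convenience wrapper: average nominal trajectory from the training set's
#' nominal trials, weight optimisation, and Riccati gains.
#'
#' @param train a [TrainingSet-class].
#' @param params a [TipmParams-class].
#' @param dt time step (default 0.005).
#' @return An [LqrController-class].
#' @export
fitLqr <- function(train, params, dt = 0.005) {
  nom <- Filter(function(tr) tr@trialType == "nominal", train@trials)
  if (length(nom) == 0) nom <- train@trials
  avg <- averageNominal(nom, params)
  w <- optimizeLqrWeights(train, avg, params, dt = dt)
  K <- fitLqrGains(w$Q, w$R, params, dt = dt)
  new("LqrController", tGrid = avg@tGrid, strategy = train@strategy,
      Q = w$Q, R = w$R, K = K, avg = avg)
}

#' Fit the feed-forward plus feedback controller
#'
#' At every grid point, solves the linear least-squares problem
#' \eqn{u_i(t) \approx ff(t) - K(t) x_i(t)} over the valid training samples.
#' A ridge penalty (default 1e-4, scaled to the state magnitudes) on K keeps
#' the per-step normal equations well conditioned: the per-step state clouds
#' of real and synthetic trials are nearly collinear, and an unpenalised fit
#' would return feedback gains large enough to overflow the closed-loop
#' matrix exponential downstream. With fewer distinct states than unknowns
#' this yields the minimum-feedback solution (K pushed towards zero, ff
#' carrying the mean input).
#'
#' @param train a [TrainingSet-class].
#' @param ridge ridge penalty on the feedback entries (default 1e-4).
#' @return An [FfFbController-class].
#' @export
fitFfFb <- function(train, ridge = 1e-4) {
  trials <- train@trials
  tg <- trials[[1]]@tGrid
  nT <- length(tg)
  ff <- matrix(NA_real_, nT, 2)
  K <- array(NA_real_, c(2, 4, nT))
  for (k in seq_len(nT)) {
    use <- vapply(trials, function(tr) tr@validMask[k], logical(1))
    if (!any(use))
      stop("fitFfFb: no valid training samples at t = ", format(tg[k]))
    Xk <- t(vapply(trials[use], function(tr) tr@state[k, ], numeric(4)))
    Uk <- t(vapply(trials[use], function(tr) tr@input[k, ], numeric(2)))
    A <- cbind(1, -Xk)                       # u = ff - K x
    scl <- ridge * (1 + mean(rowSums(Xk^2)))
    AtA <- crossprod(A) + scl * diag(c(0, rep(1, 4)))
    theta <- solve(AtA, crossprod(A, Uk))    # 5 x 2
    ff[k, ] <- theta[1, ]
    K[, , k] <- t(theta[2:5, ])
  }
  new("FfFbController", tGrid = tg, strategy = train@strategy, ff = ff, K = K)
}

# one per-row input-bounds QP: unknowns z = (b_lb, b_ub, k1..k4)
# min sum_i (b_lb - k'x_i - u_i)^2 + (b_ub - k'x_i - u_i)^2
# s.t. b_lb - k'x_i <= u_i <= b_ub - k'x_i
.inputBoundsQp <- function(Xk, u, ridge = 1e-8) {
  n <- length(u)
  Aeq <- cbind(1, 0, -Xk)   # rows a_i' (b_lb block)
  Ceq <- cbind(0, 1, -Xk)   # rows c_i' (b_ub block)
  D <- 2 * (crossprod(Aeq) + crossprod(Ceq))
  scl <- ridge * (1 + sum(diag(D)) / 6)
  D <- D + 2 * scl * diag(c(0, 0, rep(1, 4)))
  dv <- 2 * (crossprod(Aeq, u) + crossprod(Ceq, u))
  # constraints A'z >= b0; for coincident states (all trials start from the
  # same seated posture, so this happens at t = 0) only the extreme inputs
  # can bind, and duplicated constraint rows make the active-set solver cycle
  gkey <- apply(round(Xk, 9), 1, paste, collapse = ",")
  lowIdx <- vapply(split(seq_len(n), gkey),
                   function(ii) ii[which.min(u[ii])], integer(1))
  upIdx <- vapply(split(seq_len(n), gkey),
                  function(ii) ii[which.max(u[ii])], integer(1))
  Amat <- t(rbind(cbind(-1, 0, Xk[lowIdx, , drop = FALSE]),
                  cbind(0, 1, -Xk[upIdx, , drop = FALSE])))
  bvec <- c(-u[lowIdx], u[upIdx])
  sol <- quadprog::solve.QP(D, dv, Amat, bvec)
  z <- sol$solution
  list(bl = z[1], bu = z[2], k = z[3:6],
       # objective of the original (unridged) program
       value = sum((z[1] - Xk %*% z[3:6] - u)^2) +
         sum((z[2] - Xk %*% z[3:6] - u)^2))
}

#' Fit the input-bounds controller
#'
#' Per grid point and input dimension (the two input rows decouple in both
#' objective and constraints), solves the constrained least-squares quadratic
#' program that places a lower and an upper bounded component around the
#' observed inputs, sharing one feedback row: every valid training input is
#' forced inside the band, and the band hugs the data as tightly as the
#' least-squares objective allows. If the QP solver fails at a step, the
#' always-feasible fallback (zero feedback, band = data range) is used.
#'
#' @param train a [TrainingSet-class].
#' @param ridge ridge on the feedback row, scaled to the state magnitudes,
#'   keeping the gains bounded when the per-step state cloud is nearly
#'   collinear (default 1e-4).
#' @param tol constraint verification tolerance (default 1e-7).
#' @return An [InputBoundsController-class].
#' @export
fitInputBounds <- function(train, ridge = 1e-4, tol = 1e-7) {
  trials <- train@trials
  tg <- trials[[1]]@tGrid
  nT <- length(tg)
  bLb <- matrix(NA_real_, nT, 2)
  bUb <- matrix(NA_real_, nT, 2)
  K <- array(NA_real_, c(2, 4, nT))
  for (k in seq_len(nT)) {
    use <- vapply(trials, function(tr) tr@validMask[k], logical(1))
    if (!any(use))
      stop("fitInputBounds: no valid training samples at t = ", format(tg[k]))
    Xk <- t(vapply(trials[use], function(tr) tr@state[k, ], numeric(4)))
    Uk <- t(vapply(trials[use], function(tr) tr@input[k, ], numeric(2)))
    for (r in 1:2) {
      fit <- tryCatch(.inputBoundsQp(Xk, Uk[, r], ridge = ridge),
                      error = function(e) NULL)
      if (is.null(fit)) { # guaranteed-feasible fallback
        fit <- list(bl = min(Uk[, r]), bu = max(Uk[, r]), k = rep(0, 4))
      }
      resid <- Xk %*% fit$k
      if (any(fit$bl - resid > Uk[, r] + tol) ||
          any(fit$bu - resid < Uk[, r] - tol))
        stop("fitInputBounds: QP constraints violated at step ", k,
             " beyond tolerance ", tol)
      # snap inward violations within tolerance so the band truly covers
      slack <- max(0, max(fit$bl - resid - Uk[, r]), 0)
      bLb[k, r] <- fit$bl - slack
      bUb[k, r] <- fit$bu + max(0, max(Uk[, r] - (fit$bu - resid)))
      K[r, , k] <- fit$k
    }
    # the two rows share K in the model definition; the QP solves them with
    # independent rows, so the stored gain keeps both rows (2 x 4).
  }
  new("InputBoundsController", tGrid = tg, strategy = train@strategy,
      bLb = bLb, bUb = bUb, K = K)
}

# ---- evaluation ------------------------------------------------------------

.checkT <- function(t) {
  if (t < -1e-12 || t > 1 + 1e-12)
    stop("controller evaluated outside [0, 1]: t = ", format(t))
  min(max(t, 0), 1)
}

setMethod("evalController", signature("LqrController", "numeric", "numeric"),
  function(ctrl, t, x) {
    t <- .checkT(t)
    uol <- .interpRows(ctrl@avg@uOl, ctrl@tGrid, t)
    xbar <- .interpRows(ctrl@avg@xBar, ctrl@tGrid, t)
    K <- .interpGain(ctrl@K, ctrl@tGrid, t)
    as.numeric(uol - K %*% (x - xbar))
  })

setMethod("evalController", signature("FfFbController", "numeric", "numeric"),
  function(ctrl, t, x) {
    t <- .checkT(t)
    ff <- .interpRows(ctrl@ff, ctrl@tGrid, t)
    K <- .interpGain(ctrl@K, ctrl@tGrid, t)
    as.numeric(ff - K %*% x)
  })

setMethod("evalController",
  signature("InputBoundsController", "numeric", "numeric"),
  function(ctrl, t, x) {
    t <- .checkT(t)
    bl <- .interpRows(ctrl@bLb, ctrl@tGrid, t)
    bu <- .interpRows(ctrl@bUb, ctrl@tGrid, t)
    K <- .interpGain(ctrl@K, ctrl@tGrid, t)
    fb <- as.numeric(K %*% x)
    rbind(lb = bl - fb, ub = bu - fb)
  })

setMethod("closedLoopSystem",
  signature("LqrController", "numeric", "TipmParams"),
  function(ctrl, t, params) {
    t <- .checkT(t)
    B <- .tipmB(params@mass)
    K <- .interpGain(ctrl@K, ctrl@tGrid, t)
    uol <- .interpRows(ctrl@avg@uOl, ctrl@tGrid, t)
    xbar <- .interpRows(ctrl@avg@xBar, ctrl@tGrid, t)
    w <- as.numeric(B %*% (uol + K %*% xbar)) + .gravityOffset(params)
    list(Acl = .tipmA() - B %*% K, W = Zonotope(w))
  })

setMethod("closedLoopSystem",
  signature("FfFbController", "numeric", "TipmParams"),
  function(ctrl, t, params) {
    t <- .checkT(t)
    B <- .tipmB(params@mass)
    K <- .interpGain(ctrl@K, ctrl@tGrid, t)
    ff <- .interpRows(ctrl@ff, ctrl@tGrid, t)
    w <- as.numeric(B %*% ff) + .gravityOffset(params)
    list(Acl = .tipmA() - B %*% K, W = Zonotope(w))
  })

setMethod("closedLoopSystem",
  signature("InputBoundsController", "numeric", "TipmParams"),
  function(ctrl, t, params) {
    t <- .checkT(t)
    B <- .tipmB(params@mass)
    K <- .interpGain(ctrl@K, ctrl@tGrid, t)
    bl <- .interpRows(ctrl@bLb, ctrl@tGrid, t)
    bu <- .interpRows(ctrl@bUb, ctrl@tGrid, t)
    ctr <- as.numeric(B %*% ((bl + bu) / 2)) + .gravityOffset(params)
    Gin <- B %*% diag((bu - bl) / 2, 2)
    keep <- colSums(abs(Gin)) > 0
    W <- Zonotope(ctr, Gin[, keep, drop = FALSE])
    list(Acl = .tipmA() - B %*% K, W = W)
  })
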