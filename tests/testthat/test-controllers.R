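# build a NormalizedTrial directly from state/input trajectories generated
# under a known control law (duration = Tbar so inverse dynamics is exact)
lawTrial <- function(x0, law, params, label = "success",
                     type = "nominal") {
  tg <- seq(0, 1, length.out = 201)
  traj <- simulateForward(x0, law, NULL, params)
  u <- t(vapply(seq_along(tg), function(k) law(tg[k], traj[k, ]),
                numeric(2)))
  m <- params@mass
  acc <- cbind(u[, 1] / m, u[, 2] / m - params@g * params@Tbar^2)
  new("NormalizedTrial", tGrid = tg, state = traj, acc = acc,
      dist = matrix(0, 201, 2), input = matrix(numeric(0), 0, 2),
      validMask = rep(TRUE, 201), toeX = numeric(0),
      duration = params@Tbar, strategy = "natural", trialType = type,
      pertWindow = numeric(0), label = label, subjectMass = m)
}

test_that("training sets take successful same-strategy trials only", {
  d <- tinyData()
  train <- tinyTrain()
  expect_true(all(vapply(train@trials, function(tr) nrow(tr@input) == 201,
                         logical(1))))
  nominal <- Filter(function(tr) tr@trialType == "nominal", train@trials)
  expect_true(all(vapply(nominal, function(tr) all(tr@validMask),
                         logical(1))))
  pert <- Filter(function(tr) tr@trialType == "perturbed", train@trials)
  for (tr in pert) {
    expect_identical(!tr@validMask,
                     tr@tGrid >= tr@pertWindow[1] &
                       tr@tGrid <= tr@pertWindow[2])
  }
  fails <- Filter(function(tr) tr@label != "success", d$ntr)
  expect_error(buildTrainingSet(c(d$succ[1], fails[1]), d$params),
               "success")
  other <- d$succ[[1]]; other@strategy <- "quasi_static"
  expect_error(buildTrainingSet(list(d$succ[[2]], other), d$params),
               "strategies")
})

test_that("the average nominal trajectory is consistent with its input", {
  d <- tinyData()
  nom <- Filter(function(tr) tr@trialType == "nominal", d$succ)
  avg <- averageNominal(nom, d$params)
  expect_equal(avg@xBar,
               Reduce(`+`, lapply(nom, function(tr) tr@state)) / length(nom))
  # identical trials average to themselves
  same <- averageNominal(list(nom[[1]], nom[[1]]), d$params)
  expect_equal(same@xBar, nom[[1]]@state)
  # mirrored deviations cancel to the midline
  a <- nom[[1]]; b <- nom[[1]]
  a@state <- a@state + 0.05
  b@state <- b@state - 0.05
  expect_equal(averageNominal(list(a, b), d$params)@xBar, nom[[1]]@state)
  # u_ol recomputed from the mean accelerations reproduces the mean motion
  params <- tipmParams(d$cfg@mass, nom[[1]]@duration)
  avg2 <- averageNominal(nom, params)
  sim <- simulateForward(avg2@xBar[1, ], avg2@uOl, NULL, params)
  expect_lt(max(abs(sim - avg2@xBar)), 5e-3)
  expect_error(averageNominal(list(), d$params), "no nominal")
})

test_that("Riccati gains vanish as control becomes expensive", {
  params <- tipmParams(65.4, 1.2)
  Kcheap <- fitLqrGains(diag(4), diag(2) * 1e-9, params)
  Kdear <- fitLqrGains(diag(4), diag(2) * 1e9, params)
  expect_lt(max(abs(Kdear)), 1e-6 * max(abs(Kcheap)))
  expect_error(fitLqrGains(diag(c(1, -1, 1, 1)), diag(2), params),
               "positive definite")
})

test_that("the LQR law returns the open-loop input on the nominal path", {
  d <- tinyData()
  nom <- Filter(function(tr) tr@trialType == "nominal", d$succ)
  avg <- averageNominal(nom, d$params)
  K <- fitLqrGains(diag(c(1, 5, 20, 2)), diag(c(1e-3, 1e-3)), d$params)
  ctrl <- new("LqrController", tGrid = avg@tGrid, strategy = "natural",
              Q = diag(c(1, 5, 20, 2)), R = diag(c(1e-3, 1e-3)),
              K = K, avg = avg)
  for (t in c(0, 0.25, 0.5, 1)) {
    k <- round(t * 200) + 1
    expect_equal(evalController(ctrl, t, avg@xBar[k, ]), avg@uOl[k, ],
                 tolerance = 1e-9)
  }
  expect_error(evalController(ctrl, 1.2, avg@xBar[201, ]), "outside")
})

test_that("weight optimisation recovers an LQR that generated the data", {
  params <- tipmParams(65.4, 1.2)
  d <- tinyData()
  nom <- Filter(function(tr) tr@trialType == "nominal", d$succ)
  avg <- averageNominal(nom, params)
  Qs <- diag(c(1, 5, 20, 2)); Rs <- diag(c(1e-3, 1e-3))
  Ks <- fitLqrGains(Qs, Rs, params)
  ctrlTrue <- new("LqrController", tGrid = avg@tGrid, strategy = "natural",
                  Q = Qs, R = Rs, K = Ks, avg = avg)
  set.seed(9)
  trials <- lapply(1:6, function(i) {
    x0 <- avg@xBar[1, ] + stats::rnorm(4, 0, c(0.03, 0.05, 0.02, 0.04))
    lawTrial(x0, function(t, x) evalController(ctrlTrue, t, x), params)
  })
  train <- buildTrainingSet(trials, params)
  w <- optimizeLqrWeights(train, avg, params)
  # box constraints honoured
  expect_true(all(diag(w$Q)[2:4] >= 0.1 - 1e-9 & diag(w$Q)[2:4] <= 100 + 1e-9))
  expect_true(w$R[1, 1] >= 1e-5 - 1e-12 && w$R[1, 1] <= 1e-2 + 1e-12)
  expect_true(w$R[2, 2] >= 1e-6 - 1e-12 && w$R[2, 2] <= 1e-1 + 1e-12)
  # the minimiser dominates the generating weights
  arr <- StabilityBasin:::.trainingArrays(train)
  directObj <- function(Q, R) {
    K <- fitLqrGains(Q, R, params)
    ctrl <- new("LqrController", tGrid = avg@tGrid, strategy = "natural",
                Q = Q, R = R, K = K, avg = avg)
    s <- 0
    for (k in 1:200) {
      for (i in seq_along(trials)) {
        u <- evalController(ctrl, avg@tGrid[k], arr$X[, k, i])
        s <- s + sum((u - arr$U[, k, i])^2)
      }
    }
    s
  }
  expect_lte(w$value, directObj(Qs, Rs) + 1e-6)
  # objective value agrees with an independent re-evaluation of the fit
  expect_equal(w$value, directObj(w$Q, w$R), tolerance = 1e-6)
  # gains recovered (weights only up to per-axis scale, which K quotients out)
  Kf <- fitLqrGains(w$Q, w$R, params)
  expect_lt(max(abs(Kf - Ks)), 1e-2)
})

test_that("feed-forward plus feedback regression fits and interpolates", {
  params <- tipmParams(65.4, 1.2)
  d <- tinyData()
  # data generated exactly by a known (ff*, K*): near-zero residuals
  Ks <- matrix(c(25, 9, 1, 0.5, 2, 0.3, 31, 12), 2, 4, byrow = TRUE)
  ffs <- c(15, 780)
  set.seed(11)
  trials <- lapply(1:6, function(i) {
    x0 <- c(-0.25, 0, 0.58, 0) + stats::rnorm(4, 0, 0.05)
    lawTrial(x0, function(t, x) as.numeric(ffs - Ks %*% x), params)
  })
  train <- buildTrainingSet(trials, params)
  fit <- fitFfFb(train, ridge = 1e-10)
  for (k in c(1, 51, 101, 201)) {
    for (i in 1:6) {
      x <- trials[[i]]@state[k, ]
      pred <- fit@ff[k, ] - as.numeric(fit@K[, , k] %*% x)
      expect_equal(pred, as.numeric(ffs - Ks %*% x), tolerance = 1e-6)
    }
  }
  # a single trial: minimum-feedback fit passes through its (x, u) exactly
  one <- buildTrainingSet(trials[1], params)
  fit1 <- fitFfFb(one)
  for (k in c(1, 101, 201)) {
    tr1 <- one@trials[[1]]
    pred <- fit1@ff[k, ] - as.numeric(fit1@K[, , k] %*% tr1@state[k, ])
    expect_equal(pred, tr1@input[k, ], tolerance = 1e-6)
  }
  # identical states with differing inputs: prediction is their mean
  twin <- trials[c(1, 1)]
  twin[[2]]@acc <- twin[[2]]@acc + 0.5   # shifts inputs, not states
  tw <- buildTrainingSet(twin, params)
  ftw <- fitFfFb(tw)
  predicted <- ftw@ff[101, ] - as.numeric(ftw@K[, , 101] %*%
                                            twin[[1]]@state[101, ])
  expect_equal(predicted,
               (tw@trials[[1]]@input[101, ] + tw@trials[[2]]@input[101, ]) / 2,
               tolerance = 1e-6)
  # K = 0 makes the law state-independent
  ftw@K[] <- 0
  expect_equal(evalController(ftw, 0.5, c(1, 1, 1, 1)),
               evalController(ftw, 0.5, c(-9, 2, 0, 5)))
})

test_that("input bounds enclose every valid training input", {
  train <- tinyTrain()
  ib <- fitInputBounds(train)
  expect_true(all(ib@bLb <= ib@bUb + 1e-9))
  worst <- 0
  for (tr in train@trials) {
    for (k in which(tr@validMask)) {
      fb <- as.numeric(ib@K[, , k] %*% tr@state[k, ])
      worst <- max(worst,
                   (ib@bLb[k, ] - fb) - tr@input[k, ],
                   tr@input[k, ] - (ib@bUb[k, ] - fb))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("a single trial gives a degenerate input band", {
  params <- tipmParams(65.4, 1.2)
  d <- tinyData()
  one <- buildTrainingSet(d$succ[1], params)
  ib <- fitInputBounds(one)
  tr <- one@trials[[1]]
  for (k in c(1, 101, 201)) {
    iv <- evalController(ib, tr@tGrid[k], tr@state[k, ])
    expect_equal(iv["lb", ], iv["ub", ], tolerance = 1e-5)
    expect_equal(unname(iv["lb", ]), tr@input[k, ], tolerance = 1e-5)
  }
})

test_that("the input-bounds QP matches an independent solver", {
  skip_if_not_installed("kernlab")
  set.seed(11)
  for (n in c(2, 4, 7, 10)) {
    Xk <- matrix(stats::rnorm(n * 4), n, 4)
    u <- stats::rnorm(n)
    fit <- StabilityBasin:::.inputBoundsQp(Xk, u, ridge = 1e-9)
    Aeq <- cbind(1, 0, -Xk); Ceq <- cbind(0, 1, -Xk)
    D <- 2 * (crossprod(Aeq) + crossprod(Ceq))
    scl <- 1e-9 * (1 + sum(diag(D)) / 6)
    D <- D + 2 * scl * diag(c(0, 0, rep(1, 4)))
    dv <- 2 * (crossprod(Aeq, u) + crossprod(Ceq, u))
    cap <- utils::capture.output(ip <- kernlab::ipop(
      c = -dv, H = D, A = rbind(cbind(-1, 0, Xk), cbind(0, 1, -Xk)),
      b = c(-u, u), r = rep(1e8, 2 * n), l = rep(-1e6, 6), u = rep(1e6, 6),
      sigf = 9, maxiter = 300))
    z <- kernlab::primal(ip)
    objfun <- function(z) sum((z[1] - Xk %*% z[3:6] - u)^2) +
      sum((z[2] - Xk %*% z[3:6] - u)^2)
    expect_lt(abs(fit$value - objfun(z)), 1e-6 * (1 + abs(fit$value)))
  }
})

test_that("input-bounds evaluation returns the interval", {
  train <- tinyTrain()
  ib <- fitInputBounds(train)
  iv <- evalController(ib, 0.5, train@trials[[1]]@state[101, ])
  expect_identical(rownames(iv), c("lb", "ub"))
  expect_true(all(iv["lb", ] <= iv["ub", ] + 1e-9))
  expect_error(evalController(ib, -0.2, rep(0, 4)), "outside")
})

test_that("controller fitting is deterministic", {
  train <- tinyTrain()
  p <- tinyData()$params
  expect_identical(fitInputBounds(train), fitInputBounds(train))
  expect_identical(fitFfFb(train), fitFfFb(train))
  expect_identical(fitLqr(train, p)@K, fitLqr(train, p)@K)
})
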