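# test-local controller stub with prescribed closed-loop dynamics, so the
# propagation step can be exercised on exactly solvable systems
setClass("ConstClController", contains = "StsController",
         representation(Acl = "matrix", W = "Zonotope"))
setMethod("closedLoopSystem",
          signature("ConstClController", "numeric", "TipmParams"),
          function(ctrl, t, params) list(Acl = ctrl@Acl, W = ctrl@W))

constCl <- function(Acl, W) {
  new("ConstClController", tGrid = seq(0, 1, length.out = 201),
      strategy = "natural", Acl = Acl, W = W)
}

test_that("the target set encloses all successful final states", {
  d <- tinyData()
  train <- tinyTrain()
  XT <- buildTargetSet(train)
  finals <- t(vapply(train@trials, function(tr) tr@state[201, ], numeric(4)))
  expect_true(all(vapply(seq_len(nrow(finals)), function(i)
    containsPoint(XT, finals[i, ])$inside, logical(1))))
  expect_lte(nGenerators(XT), 4)

  one <- buildTargetSet(buildTrainingSet(d$succ[1], d$params))
  expect_equal(center(one), d$succ[[1]]@state[201, ],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(generators(one) == 0))

  # rectangle of final states (distinct side lengths, so the principal
  # directions are the axes): oriented box scaled 1.05
  corners <- list(c(0, 0.1, 0.9, 0), c(0.2, 0.1, 0.9, 0),
                  c(0, 0.5, 0.9, 0), c(0.2, 0.5, 0.9, 0))
  trs <- lapply(corners, function(xf) {
    tr <- d$succ[[1]]
    tr@state[201, ] <- xf
    tr
  })
  Z <- buildTargetSet(buildTrainingSet(trs, d$params))
  halves <- sort(rowSums(abs(generators(Z))), decreasing = TRUE)
  expect_equal(halves[1:2], c(0.21, 0.105), tolerance = 1e-9)
  expect_equal(center(Z), c(0.1, 0.3, 0.9, 0), tolerance = 1e-9)
})

test_that("closed-loop systems substitute the controller into the dynamics", {
  params <- tipmParams(65.4, 1.2)
  tg <- seq(0, 1, length.out = 201)
  ffc <- new("FfFbController", tGrid = tg, strategy = "natural",
             ff = matrix(c(5, 700), 201, 2, byrow = TRUE),
             K = array(0, c(2, 4, 201)))
  cl <- closedLoopSystem(ffc, 0.3, params)
  expect_equal(cl$Acl, StabilityBasin:::.tipmA())
  expect_equal(nGenerators(cl$W), 0)
  expect_equal(center(cl$W),
               as.numeric(StabilityBasin:::.tipmB(65.4) %*% c(5, 700)) +
                 c(0, 0, 0, -9.81 * 1.2^2))

  ibc <- new("InputBoundsController", tGrid = tg, strategy = "natural",
             bLb = matrix(c(-10, 600), 201, 2, byrow = TRUE),
             bUb = matrix(c(30, 800), 201, 2, byrow = TRUE),
             K = array(0, c(2, 4, 201)))
  cl <- closedLoopSystem(ibc, 0.5, params)
  expect_equal(nGenerators(cl$W), 2)   # one interval per input dimension
  ibc@bUb <- ibc@bLb
  expect_equal(nGenerators(closedLoopSystem(ibc, 0.5, params)$W), 0)
})

test_that("one backward step follows the frozen reversed flow", {
  params <- tipmParams(65.4, 1.2)
  Z <- Zonotope(c(0.1, 0.2, 0.9, 0.1), diag(4) * 0.05)

  frozen <- constCl(matrix(0, 4, 4), Zonotope(rep(0, 4)))
  expect_equal(backwardReachStep(Z, frozen, 1, params = params), Z)

  w <- c(1, -2, 0.5, 3)
  drift <- constCl(matrix(0, 4, 4), Zonotope(w))
  Zd <- backwardReachStep(Z, drift, 1, params = params)
  expect_equal(center(Zd), center(Z) - w * 0.005, tolerance = 1e-12)
  expect_equal(generators(Zd), generators(Z))

  expect_error(backwardReachStep(Z, drift, 0.001, params = params),
               "leave")
})

test_that("backward propagation is exact for an LTI singleton system", {
  params <- tipmParams(65.4, 1.2)
  Kc <- matrix(c(30, 12, 0, 0, 0, 0, 45, 16), 2, 4, byrow = TRUE)
  ffc <- c(20, 700)
  tg <- seq(0, 1, length.out = 201)
  ctrl <- new("FfFbController", tGrid = tg, strategy = "natural",
              ff = matrix(ffc, 201, 2, byrow = TRUE),
              K = array(rep(Kc, 201), c(2, 4, 201)))
  xT <- c(0.0, 0.3, 0.95, 0.2)
  basin <- computeBasin(ctrl, Zonotope(xT), params)
  A <- StabilityBasin:::.tipmA()
  B <- StabilityBasin:::.tipmB(65.4)
  Acl <- A - B %*% Kc
  w <- as.numeric(B %*% ffc) + c(0, 0, 0, -9.81 * 1.2^2)
  E <- expm::expm(rbind(cbind(Acl, w), 0))
  x0 <- solve(E[1:4, 1:4], xT - E[1:4, 5])
  expect_lt(max(abs(center(basinSlice(basin, 0)) - x0)), 1e-6)
  # soundness: the slice-0 centre flows forward into the target
  law <- function(t, x) evalController(ctrl, t, x)
  fwd <- simulateForward(center(basinSlice(basin, 0)), law, NULL, params)
  expect_lt(max(abs(fwd[201, ] - xT)), 1e-5)
})

test_that("basins have the documented slice structure", {
  params <- tipmParams(65.4, 1.2)
  tg <- seq(0, 1, length.out = 201)
  ibc <- new("InputBoundsController", tGrid = tg, strategy = "natural",
             bLb = matrix(c(-20, 650), 201, 2, byrow = TRUE),
             bUb = matrix(c(20, 900), 201, 2, byrow = TRUE),
             K = array(rep(c(10, 6, 0, 0, 0, 0, 14, 8), 201), c(2, 4, 201)))
  XT <- Zonotope(c(0, 0.2, 0.95, 0.1), diag(4) * 0.03)
  basin <- computeBasin(ibc, XT, params)
  expect_length(basinSlices(basin), 201)
  expect_equal(basin@dt, 0.005)
  expect_equal(basinSlice(basin, 1), XT)
  expect_true(all(vapply(basinSlices(basin), nGenerators, integer(1)) <= 800))

  # stationary-target fixed point: gravity-cancelling input, zero feedback,
  # zero-velocity singleton target stays put under the backward flow
  ffc <- new("FfFbController", tGrid = tg, strategy = "natural",
             ff = matrix(c(0, 65.4 * 9.81 * 1.2^2), 201, 2, byrow = TRUE),
             K = array(0, c(2, 4, 201)))
  rest <- Zonotope(c(0.1, 0, 0.9, 0))
  fb <- computeBasin(ffc, rest, params)
  for (k in c(1, 101, 201))
    expect_equal(center(basinSlices(fb)[[k]]), center(rest),
                 tolerance = 1e-10)

  # the centre flows to the target centre under the mid-band input
  ctr0 <- center(basinSlice(basin, 0))
  midLaw <- function(t, x) {
    iv <- evalController(ibc, t, x)
    (iv["lb", ] + iv["ub", ]) / 2
  }
  fwd <- simulateForward(ctr0, midLaw, NULL, params)
  expect_lt(max(abs(fwd[201, ] - center(XT))), 1e-4)
})

test_that("widening input bounds never shrinks the basin", {
  params <- tipmParams(65.4, 1.2)
  tg <- seq(0, 1, length.out = 201)
  base <- new("InputBoundsController", tGrid = tg, strategy = "natural",
              bLb = matrix(c(-20, 650), 201, 2, byrow = TRUE),
              bUb = matrix(c(20, 900), 201, 2, byrow = TRUE),
              K = array(rep(c(10, 6, 0, 0, 0, 0, 14, 8), 201),
                        c(2, 4, 201)))
  wide <- base
  wide@bLb <- base@bLb - 15
  wide@bUb <- base@bUb + 15
  XT <- Zonotope(c(0, 0.2, 0.95, 0.1), diag(4) * 0.03)
  bN <- computeBasin(base, XT, params)
  bW <- computeBasin(wide, XT, params)
  set.seed(13)
  for (t in c(0, 0.35, 0.7)) {
    pts <- sampleZonotope(basinSlice(bN, t), 8)
    for (i in seq_len(nrow(pts)))
      expect_true(containsPoint(basinSlice(bW, t), pts[i, ],
                                tol = 1e-7)$inside)
  }
})

test_that("tightening the generator cap keeps an outer approximation", {
  params <- tipmParams(65.4, 1.2)
  tg <- seq(0, 1, length.out = 201)
  ibc <- new("InputBoundsController", tGrid = tg, strategy = "natural",
             bLb = matrix(c(-20, 650), 201, 2, byrow = TRUE),
             bUb = matrix(c(20, 900), 201, 2, byrow = TRUE),
             K = array(rep(c(10, 6, 0, 0, 0, 0, 14, 8), 201), c(2, 4, 201)))
  XT <- Zonotope(c(0, 0.2, 0.95, 0.1), diag(4) * 0.03)
  bFull <- computeBasin(ibc, XT, params, maxGenerators = 800)
  bCap <- computeBasin(ibc, XT, params, maxGenerators = 40)
  expect_true(all(vapply(basinSlices(bCap), nGenerators, integer(1)) <= 40))
  set.seed(14)
  for (t in c(0, 0.5)) {
    pts <- sampleZonotope(basinSlice(bFull, t), 8)
    for (i in seq_len(nrow(pts)))
      expect_true(containsPoint(basinSlice(bCap, t), pts[i, ],
                                tol = 1e-7)$inside)
  }
})

test_that("the naive basin wraps the observed states without dynamics", {
  train <- tinyTrain()
  params <- tinyData()$params
  nb <- computeNaiveBasin(train, params)
  expect_identical(nb@controllerType, "naive")
  for (k in c(1, 51, 101, 151, 201)) {
    for (tr in train@trials)
      expect_true(containsPoint(basinSlices(nb)[[k]], tr@state[k, ],
                                tol = 1e-7)$inside)
  }
  # a single trial gives a basin of singletons tracing its trajectory
  one <- computeNaiveBasin(buildTrainingSet(tinyData()$succ[1],
                                            params), params)
  for (k in c(1, 101, 201)) {
    expect_equal(center(basinSlices(one)[[k]]),
                 tinyData()$succ[[1]]@state[k, ], tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(generators(basinSlices(one)[[k]]) == 0))
  }
})

test_that("basin dilation scales slices and is containment-monotone", {
  train <- tinyTrain()
  params <- tinyData()$params
  nb <- computeNaiveBasin(train, params)
  same <- dilateBasin(nb, 1)
  expect_equal(same@slices, nb@slices)
  d105 <- dilateBasin(nb, 1.05)
  expect_equal(d105@dilation, 1.05)
  expect_equal(generators(basinSlices(d105)[[101]]),
               1.05 * generators(basinSlices(nb)[[101]]))
  expect_equal(center(basinSlices(d105)[[101]]),
               center(basinSlices(nb)[[101]]))
  # any point inside a slice stays inside the dilated slice
  set.seed(15)
  pts <- sampleZonotope(basinSlices(nb)[[51]], 25)
  for (i in seq_len(nrow(pts)))
    expect_true(containsPoint(basinSlices(d105)[[51]], pts[i, ])$inside)
})
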