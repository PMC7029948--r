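tg201 <- seq(0, 1, length.out = 201)

test_that("step detection uses a strict displacement threshold", {
  expect_true(is.na(detectStep(rep(0.02, 201), tg201)))
  # ramp that first exceeds 0.0762 m at the grid point t = 0.60
  toe <- rep(0, 201)
  toe[tg201 >= 0.6] <- 0.08
  expect_equal(detectStep(toe, tg201), 0.6)
  # exactly at the threshold: not a step ("more than")
  expect_true(is.na(detectStep(c(rep(0, 100), rep(0.0762, 101)), tg201)))
  expect_error(detectStep(numeric(0), tg201), "toe")
})

test_that("sit detection needs both velocities negative, persistently", {
  vx <- rep(0.2, 201); vy <- rep(0.1, 201)
  expect_true(is.na(detectSit(vx, vy, tg201)))
  # both negative from the 150th sample on: onset at t = 0.745
  vx2 <- vx; vy2 <- vy
  vx2[150:201] <- -0.1; vy2[150:201] <- -0.2
  expect_equal(detectSit(vx2, vy2, tg201), tg201[150])
  # conjunction required
  expect_true(is.na(detectSit(-vx, vy, tg201)))
  # a too-short dip is ignored, a long one is not
  vx3 <- vx; vy3 <- vy
  vx3[50:51] <- -1; vy3[50:51] <- -1
  expect_true(is.na(detectSit(vx3, vy3, tg201, persist = 3)))
  vx3[50:53] <- -1; vy3[50:53] <- -1
  expect_equal(detectSit(vx3, vy3, tg201, persist = 3), tg201[50])
})

test_that("failure assignment takes the earlier event and clamps to 1", {
  expect_identical(assignFailure(NA, NA),
                   list(label = "success", tF = NA_real_))
  expect_identical(assignFailure(0.9, 0.8), list(label = "sit", tF = 0.8))
  expect_identical(assignFailure(0.8, 0.9), list(label = "step", tF = 0.8))
  # onset after the defined trial end: unsuccessful, t_f clamped to 1
  expect_identical(assignFailure(1.07, NA), list(label = "step", tF = 1))
  # order of arguments must not matter for the winning label
  expect_identical(assignFailure(0.7, 0.9)$label,
                   assignFailure(0.7, 0.9)$label)
})

# a hand-built basin whose slices are boxes around a prescribed trajectory
boxBasin <- function(centers, half = 0.1, params = tipmParams(70, 1)) {
  slices <- lapply(seq_len(nrow(centers)), function(k)
    Zonotope(centers[k, ], diag(4) * half))
  new("StabilityBasin", slices = slices, target = slices[[nrow(centers)]],
      controllerType = "naive", params = params, dt = 0.005,
      maxGenerators = 800, dilation = 1)
}

pathTrial <- function(states, type = "nominal", win = numeric(0),
                      label = "success") {
  new("NormalizedTrial", tGrid = tg201, state = states,
      acc = matrix(0, 201, 2), dist = matrix(0, 201, 2),
      input = matrix(numeric(0), 0, 2), validMask = rep(TRUE, 201),
      toeX = numeric(0), duration = 1, strategy = "natural",
      trialType = type, pertWindow = win, label = label, subjectMass = 70)
}

test_that("classification checks containment over the admissible window", {
  centers <- cbind(tg201, 0.5, 0.6 + 0.3 * tg201, 0.3)
  basin <- boxBasin(centers)
  onPath <- classifyTrial(basin, pathTrial(centers),
                          outcome = list(label = "success", tF = NA_real_))
  expect_identical(onPath@predicted, "success")
  expect_true(all(onPath@betaTrace == 0))
  expect_length(onPath@betaTrace, 201)

  # leaves the boxes from t = 0.6 onwards
  drift <- centers
  drift[tg201 >= 0.6, 1] <- drift[tg201 >= 0.6, 1] + 0.5
  out <- classifyTrial(basin, pathTrial(drift),
                       outcome = list(label = "success", tF = NA_real_))
  expect_identical(out@predicted, "failure")
  expect_equal(out@firstExit, 0.6)

  # restriction 1: pre-onset excursions of a perturbed trial are ignored
  pre <- centers
  pre[tg201 < 0.5, 1] <- pre[tg201 < 0.5, 1] + 5
  okPre <- classifyTrial(basin, pathTrial(pre, type = "perturbed",
                                          win = c(0.5, 0.6)),
                         outcome = list(label = "success", tF = NA_real_))
  expect_identical(okPre@predicted, "success")

  # restriction 2: post-failure excursions are ignored (window ends at t_f)
  post <- centers
  post[tg201 > 0.8, 1] <- post[tg201 > 0.8, 1] + 5
  okPost <- classifyTrial(basin, pathTrial(post, label = "sit"),
                          outcome = list(label = "sit", tF = 0.75))
  expect_identical(okPost@predicted, "success")
  expect_length(okPost@betaTrace, 151)   # slices 0 .. 0.75
})

test_that("classification is invariant to slices outside the window", {
  centers <- cbind(tg201, 0.5, 0.6 + 0.3 * tg201, 0.3)
  basin <- boxBasin(centers)
  mangled <- basin
  # corrupt slices outside [onset, t_f]: they must not matter
  for (k in c(1:99, 182:201))
    mangled@slices[[k]] <- Zonotope(rep(99, 4), diag(4) * 1e-6)
  tr <- pathTrial(centers, type = "perturbed", win = c(0.5, 0.6))
  a <- classifyTrial(basin, tr, outcome = list(label = "sit", tF = 0.9))
  b <- classifyTrial(mangled, tr, outcome = list(label = "sit", tF = 0.9))
  expect_identical(a@predicted, b@predicted)
  expect_identical(a@betaTrace, b@betaTrace)
})

test_that("observed outcomes prefer metadata and fall back to detectors", {
  d <- tinyData()
  sitTrial <- Filter(function(tr) tr@label == "sit", d$ntr)
  if (length(sitTrial) > 0) {
    oc <- suppressMessages(observedOutcome(sitTrial[[1]]))
    expect_identical(oc$label, "sit")
    expect_true(oc$tF >= 0 && oc$tF <= 1)
  }
  succ <- d$succ[[1]]
  expect_identical(observedOutcome(succ)$label, "success")
  # unknown label: detectors decide
  unk <- succ
  unk@label <- "unknown"
  expect_identical(observedOutcome(unk)$label, "success")
})

test_that("identical successful trials are all predicted successful", {
  d <- tinyData()
  trials <- d$succ[c(1, 1, 1)]
  out <- leaveOneOutEvaluate(trials, "naive", d$params)
  expect_identical(out$predicted, rep("success", 3))
})

test_that("leave-one-out matches direct per-trial classification", {
  d <- tinyData()
  ntr <- d$ntr
  out <- suppressMessages(
    leaveOneOutEvaluate(ntr, "input_bounds", d$params))
  lb <- suppressMessages(looBasins(ntr, "input_bounds", d$params))
  for (i in seq_along(ntr)) {
    pos <- match(i, lb$successIdx)
    basin <- if (!is.na(pos)) lb$heldOut[[pos]] else lb$full
    oc <- suppressMessages(
      classifyTrial(basin, ntr[[i]],
                    outcome = suppressMessages(observedOutcome(ntr[[i]]))))
    expect_identical(out$predicted[i], oc@predicted)
  }
  expect_error(leaveOneOutEvaluate(d$succ[1], "naive", d$params),
               "at least 2")
})

test_that("the naive method leaves the held-out trial out of every slice", {
  d <- tinyData()
  succ <- d$succ
  # find the trial with the most anterior COM mid-motion (strictly extremal)
  mid <- vapply(succ, function(tr) tr@state[101, 1], numeric(1))
  i <- which.max(mid)
  lb <- looBasins(succ, "naive", d$params)
  full <- basinSlices(lb$full)[[101]]
  held <- basinSlices(lb$heldOut[[match(i, lb$successIdx)]])[[101]]
  e1 <- c(1, 0, 0, 0)
  expect_lt(supportFn(held, e1), supportFn(full, e1))
})

test_that("result summaries count per strategy and category", {
  df <- data.frame(
    trialId = sprintf("t%02d", 1:14), method = "input_bounds",
    strategy = "natural",
    observed = c(rep("success", 10), rep("step", 2), rep("sit", 2)),
    tF = c(rep(NA, 10), rep(0.8, 4)),
    predicted = c(rep("success", 9), "failure",
                  "failure", "success", "failure", "failure"),
    firstExit = NA, stringsAsFactors = FALSE)
  tab <- summarizeResults(df)
  comb <- tab[tab$strategy == "combined", ]
  expect_equal(comb$success_pct, 90)
  expect_equal(comb$step_pct, 50)
  expect_equal(comb$sit_pct, 100)
  # false successes: 1 failure among 10 predicted-successful
  expect_equal(comb$false_success_pct, 10)
  # false failures: 1 success among 4 predicted-failure
  expect_equal(comb$false_failure_pct, 25)

  # an empty category yields NA, not an error
  df2 <- df[df$observed != "sit", ]
  expect_true(is.na(summarizeResults(df2)[1, "sit_pct"]))

  # 10 of 10 correct
  df3 <- df[1:9, ]
  expect_equal(summarizeResults(df3)[1, "success_pct"], 100)
})
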