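#' @include AllClasses.R AllGenerics.R reachability.R
NULL

#' Detect step onset from toe displacement
#'
#' A step is flagged at the first sample where the anterior-posterior toe
#' position has moved strictly more than `threshold` (default 0.0762 m,
#' i.e. 3 inches) from its initial value.
#'
#' @param toeX toe anterior-posterior positions (m).
#' @param tGrid matching normalised time grid.
#' @param threshold displacement threshold (m).
#' @return The normalised onset time, or `NA` if no step occurs.
#' @export
detectStep <- function(toeX, tGrid, threshold = 0.0762) {
  if (length(toeX) == 0) stop("detectStep: no toe trajectory available")
  hit <- which(abs(toeX - toeX[1]) > threshold)
  if (length(hit) == 0) return(NA_real_)
  tGrid[hit[1]]
}

#' Detect sit onset from centre-of-mass velocities
#'
#' A sit is flagged when both the horizontal and the vertical velocity of the
#' centre of mass become negative (the body moves back towards the seat). To
#' suppress single-sample numerical noise the condition must persist for at
#' least `persist` consecutive samples (default 3); the onset is the first
#' sample of the qualifying run.
#'
#' @param vx,vy velocity series on the normalised grid.
#' @param tGrid matching time grid.
#' @param persist minimum run length (samples).
#' @return The normalised onset time, or `NA` if no sit occurs.
#' @export
detectSit <- function(vx, vy, tGrid, persist = 3) {
  neg <- vx < 0 & vy < 0
  r <- rle(neg)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(r$values & r$lengths >= persist)
  if (length(ok) == 0) return(NA_real_)
  tGrid[starts[ok[1]]]
}

#' Combine step and sit detections into an outcome
#'
#' The earlier event wins; events after the trial end (t = 1, possible when
#' segmentation places the failure after the defined end of the motion) keep
#' the unsuccessful label but clamp the failure onset to 1. No event means
#' success.
#'
#' @param stepT step onset (normalised time) or `NA`.
#' @param sitT sit onset or `NA`.
#' @return A list with `label` (`"success"`, `"step"` or `"sit"`) and `tF`
#'   (failure onset, `NA` for success).
#' @export
assignFailure <- function(stepT = NA_real_, sitT = NA_real_) {
  if (is.na(stepT) && is.na(sitT))
    return(list(label = "success", tF = NA_real_))
  cand <- c(step = stepT, sit = sitT)
  lab <- names(which.min(cand))
  list(label = lab, tF = min(min(cand, na.rm = TRUE), 1))
}

#' Observed outcome of a trial
#'
#' Uses the metadata label when present; otherwise applies the step and sit
#' detection rules to the trial's toe and velocity series. When both are
#' available and disagree, the metadata wins and a message is emitted.
#'
#' @param trial a [NormalizedTrial-class].
#' @param persist sit-detection persistence (samples).
#' @return A list with `label` and `tF` as in [assignFailure()].
#' @export
observedOutcome <- function(trial, persist = 3) {
  stepT <- if (length(trial@toeX) > 0)
    detectStep(trial@toeX, trial@tGrid) else NA_real_
  sitT <- detectSit(trial@state[, 2], trial@state[, 4], trial@tGrid,
                    persist = persist)
  det <- assignFailure(stepT, sitT)
  if (trial@label != "unknown") {
    if (det$label != trial@label)
      message("observedOutcome: detector says '", det$label,
              "' but metadata says '", trial@label, "'; using metadata")
    if (trial@label == "success") return(list(label = "success", tF = NA_real_))
    tF <- if (trial@label == "step" && !is.na(stepT)) min(stepT, 1)
      else if (trial@label == "sit" && !is.na(sitT)) min(sitT, 1)
      else if (!is.na(det$tF)) det$tF
      else 1
    return(list(label = trial@label, tF = tF))
  }
  det
}

#' Classify one trial against a Stability Basin
#'
#' Checks the trial's state against the basin slice at every grid point of
#' the admissible window and predicts failure iff the state exits the basin
#' at any step. The admissible window runs from the perturbation onset (for
#' perturbed trials; predictions before the pull would be unfair to the
#' basin) to the failure onset (for unsuccessful trials; afterwards the
#' subject has already abandoned the strategy), with endpoints snapped
#' outward to whole slices.
#'
#' @param basin a [StabilityBasin-class].
#' @param trial a [NormalizedTrial-class] on the same grid.
#' @param outcome observed outcome list (`label`, `tF`) from
#'   [observedOutcome()]; computed from the trial if `NULL`.
#' @param tol containment boundary tolerance (default 1e-9).
#' @param exact passed to [containsPoint()]; the default `FALSE` uses
#'   certified bounds to short-circuit clear cases (the decision is still
#'   exact).
#' @param trialId identifier stored in the result.
#' @return A [TrialOutcome-class].
#' @export
classifyTrial <- function(basin, trial, outcome = NULL, tol = 1e-9,
                          exact = FALSE, trialId = "trial") {
  if (is.null(outcome)) outcome <- observedOutcome(trial)
  dt <- basin@dt
  n <- round(1 / dt)
  onset <- if (trial@trialType == "perturbed" &&
               length(trial@pertWindow) == 2) trial@pertWindow[1] else 0
  tEnd <- if (!is.na(outcome$tF)) min(outcome$tF, 1) else 1
  j0 <- max(floor(onset / dt + 1e-9), 0) + 1          # snap window start down
  j1 <- min(ceiling(tEnd / dt - 1e-9), n) + 1         # snap window end up
  if (j1 < j0)
    stop("classifyTrial: empty admissible window for trial ", trialId)
  beta <- rep(NA_real_, j1 - j0 + 1)
  names(beta) <- format((j0:j1 - 1) * dt)
  firstExit <- NA_real_
  for (j in j0:j1) {
    res <- containsPoint(basin@slices[[j]], trial@state[j, ], tol = tol,
                         exact = exact)
    beta[j - j0 + 1] <- res$betaMax
    if (!res$inside && is.na(firstExit)) firstExit <- (j - 1) * dt
  }
  predicted <- if (is.na(firstExit)) "success" else "failure"
  new("TrialOutcome", trialId = as.character(trialId),
      observed = outcome$label, tF = outcome$tF,
      predicted = predicted, firstExit = firstExit, betaTrace = beta)
}

#' Leave-one-out basins for one subject and strategy
#'
#' Builds everything the evaluation protocol needs: the target set from all
#' successful trials (the target set is deliberately never refit under
#' leave-one-out, since hull-edge trials would otherwise be misclassified by
#' construction), one basin per successful trial fitted without that trial,
#' and the full-data basin used for unsuccessful trials.
#'
#' @param trials list of [NormalizedTrial-class] for one subject+strategy
#'   (mixed outcomes).
#' @param method one of `"lqr"`, `"fffb"`, `"input_bounds"`, `"naive"`.
#' @param params a [TipmParams-class].
#' @param dt,maxGenerators propagation settings.
#' @param verbose emit progress messages.
#' @return A list with `heldOut` (named list of basins, one per successful
#'   trial), `full` (basin from all successful trials), `successIdx`,
#'   `target`.
#' @export
looBasins <- function(trials, method = c("input_bounds", "lqr", "fffb",
                                         "naive"),
                      params, dt = 0.005, maxGenerators = 800,
                      verbose = FALSE) {
  method <- match.arg(method)
  labels <- vapply(trials, function(tr) tr@label, character(1))
  succ <- which(labels == "success")
  if (length(succ) < 2)
    stop("looBasins: need at least 2 successful trials, got ", length(succ))
  succTrials <- trials[succ]
  target <- buildTargetSet(buildTrainingSet(succTrials, params))
  buildOne <- function(keep) {
    if (method == "naive") {
      computeNaiveBasin(buildTrainingSet(succTrials[keep], params), params,
                        dt = dt)
    } else {
      train <- buildTrainingSet(succTrials[keep], params)
      ctrl <- switch(method,
                     lqr = fitLqr(train, params, dt = dt),
                     fffb = fitFfFb(train),
                     input_bounds = fitInputBounds(train))
      computeBasin(ctrl, target, params, dt = dt,
                   maxGenerators = maxGenerators)
    }
  }
  heldOut <- vector("list", length(succ))
  names(heldOut) <- as.character(succ)
  for (i in seq_along(succ)) {
    if (verbose) message("  basin without successful trial ", i, "/",
                         length(succ))
    heldOut[[i]] <- buildOne(seq_along(succTrials)[-i])
  }
  full <- buildOne(seq_along(succTrials))
  list(heldOut = heldOut, full = full, successIdx = succ, target = target)
}

#' Leave-one-out evaluation of a Stability Basin method
#'
#' Every successful trial is classified against a basin fitted without it
#' (the target set is built once from all successful trials); every
#' unsuccessful trial is classified against the basin fitted on all
#' successful trials, using only the portion of the basin after perturbation
#' onset and before failure onset.
#'
#' @param trials list of [NormalizedTrial-class] for one subject+strategy.
#' @param method one of `"lqr"`, `"fffb"`, `"input_bounds"`, `"naive"`.
#' @param params a [TipmParams-class].
#' @param dilateFactor optional generator dilation applied to every basin
#'   before classification (default 1, none).
#' @param basins optionally, the result of [looBasins()] (reused across
#'   dilation factors); computed if `NULL`.
#' @param dt,maxGenerators propagation settings.
#' @param verbose emit progress messages.
#' @return A data frame with one row per trial: `trialId`, `method`,
#'   `observed`, `tF`, `predicted`, `firstExit`.
#' @export
leaveOneOutEvaluate <- function(trials, method = c("input_bounds", "lqr",
                                                   "fffb", "naive"),
                                params, dilateFactor = 1, basins = NULL,
                                dt = 0.005, maxGenerators = 800,
                                verbose = FALSE) {
  method <- match.arg(method)
  if (is.null(basins))
    basins <- looBasins(trials, method, params, dt = dt,
                        maxGenerators = maxGenerators, verbose = verbose)
  maybeDilate <- function(b)
    if (dilateFactor != 1) dilateBasin(b, dilateFactor) else b
  labels <- vapply(trials, function(tr) tr@label, character(1))
  ids <- names(trials)
  if (is.null(ids)) ids <- sprintf("trial%02d", seq_along(trials))
  rows <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    outc <- observedOutcome(tr)
    pos <- match(i, basins$successIdx)
    basin <- if (!is.na(pos)) basins$heldOut[[pos]] else basins$full
    oc <- classifyTrial(maybeDilate(basin), tr, outcome = outc,
                        trialId = ids[i])
    rows[[i]] <- data.frame(trialId = ids[i], method = method,
                            strategy = tr@strategy,
                            observed = oc@observed, tF = oc@tF,
                            predicted = oc@predicted,
                            firstExit = oc@firstExit,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Summarise per-trial outcomes into an accuracy table
#'
#' Counts correct predictions per strategy and category (successful trials
#' are correct when predicted successful; step and sit trials when predicted
#' failures), plus the two error rates: false successful predictions
#' (failures predicted successful, out of all predicted-successful trials)
#' and false step/sit predictions (successful trials predicted failures, out
#' of all predicted-failure trials). Empty categories are reported as 0/0
#' with an `NA` percentage.
#'
#' @param outcomes data frame from [leaveOneOutEvaluate()] (possibly several
#'   methods/strategies row-bound together).
#' @return A data frame with one row per method x strategy plus a combined
#'   row per method.
#' @export
summarizeResults <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("summarizeResults: no outcomes")
  pct <- function(k, n) if (n > 0) 100 * k / n else NA_real_
  one <- function(df, method, strategy) {
    succ <- df[df$observed == "success", ]
    step <- df[df$observed == "step", ]
    sit <- df[df$observed == "sit", ]
    predSucc <- df[df$predicted == "success", ]
    predFail <- df[df$predicted == "failure", ]
    data.frame(
      method = method, strategy = strategy,
      n_success = nrow(succ),
      success_correct = sum(succ$predicted == "success"),
      success_pct = pct(sum(succ$predicted == "success"), nrow(succ)),
      n_step = nrow(step),
      step_correct = sum(step$predicted == "failure"),
      step_pct = pct(sum(step$predicted == "failure"), nrow(step)),
      n_sit = nrow(sit),
      sit_correct = sum(sit$predicted == "failure"),
      sit_pct = pct(sum(sit$predicted == "failure"), nrow(sit)),
      false_success_pct = pct(sum(predSucc$observed != "success"),
                              nrow(predSucc)),
      false_failure_pct = pct(sum(predFail$observed == "success"),
                              nrow(predFail)),
      stringsAsFactors = FALSE)
  }
  out <- list()
  for (m in unique(outcomes$method)) {
    dfm <- outcomes[outcomes$method == m, ]
    for (s in unique(dfm$strategy))
      out[[length(out) + 1]] <- one(dfm[dfm$strategy == s, ], m, s)
    out[[length(out) + 1]] <- one(dfm, m, "combined")
  }
  do.call(rbind, out)
}
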