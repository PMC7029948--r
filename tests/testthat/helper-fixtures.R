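# Shared fixtures. Datasets are generated once per test run and cached here;
# everything is seeded through the config, so the suite is deterministic.

.fixtureCache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, force(expr), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# small single-strategy dataset: 4 nominal, 2 foot-shift, 6 perturbed
tinyData <- function() cached("tiny", {
  cfg <- syntheticConfig(seed = 7, nNominal = 4, nFootshift = 2,
                         nPerturbed = 6)
  ds <- generateDataset(cfg, strategies = "natural")
  ntr <- lapply(ds$trials, normalizeTrial)
  nomT <- vapply(Filter(function(tr) tr@trialType == "nominal", ds$trials),
                 function(tr) tr@duration, numeric(1))
  params <- tipmParams(cfg@mass, mean(nomT))
  list(cfg = cfg, raw = ds$trials, truth = ds$truth, ntr = ntr,
       params = params,
       succ = Filter(function(tr) tr@label == "success", ntr))
})

tinyTrain <- function() cached("tinyTrain", {
  d <- tinyData()
  buildTrainingSet(d$succ, d$params)
})

# fixed-duration nominal-only trials: clean ground-truth comparisons
nominalOnlyData <- function(n, seed = 123) cached(paste0("nom", n, "_", seed), {
  dur <- matrix(c(1.25, 0, 1.13, 0, 2.23, 0), 3, 2, byrow = TRUE,
                dimnames = list(c("natural", "momentum_transfer",
                                  "quasi_static"), c("mean", "sd")))
  cfg <- syntheticConfig(seed = seed, nNominal = n, nFootshift = 0,
                         nPerturbed = 0, durations = dur)
  ds <- generateDataset(cfg, strategies = "natural")
  params <- tipmParams(cfg@mass, 1.25)
  list(cfg = cfg, params = params,
       train = buildTrainingSet(lapply(ds$trials, normalizeTrial), params))
})

# exact 2-D zonotope polygon membership: generators sorted by angle give the
# vertex chain of the (convex, centrally symmetric) polygon; a point is
# inside iff it is on the inner side of every edge. Independent of the LP.
polygonContains <- function(Z, pts, tol = 1e-9) {
  G <- generators(Z)
  G <- G[, colSums(abs(G)) > 0, drop = FALSE]
  ctr <- center(Z)
  if (ncol(G) == 0) {
    d <- sqrt(colSums((t(pts) - ctr)^2))
    return(d <= tol)
  }
  flip <- G[2, ] < 0 | (G[2, ] == 0 & G[1, ] < 0)
  G[, flip] <- -G[, flip]
  ord <- order(atan2(G[2, ], G[1, ]))
  G <- G[, ord, drop = FALSE]
  # edges have the generators' directions; outward normal test per edge:
  # h(normal) = sum |normal . g|; inside iff normal.(p - c) <= h for all
  normals <- rbind(-G[2, ], G[1, ])
  h <- colSums(abs(t(normals) %*% G))
  proj <- abs(t(normals) %*% (t(pts) - ctr))
  apply(proj <= h + tol * (1 + abs(h)), 2, all)
}

# random 2-D zonotope with p generators on a sensible scale
randomZonotope2 <- function(p, scale = 1) {
  Zonotope(stats::rnorm(2, 0, scale),
           matrix(stats::rnorm(2 * p, 0, scale / sqrt(p)), 2, p))
}

# full default-protocol leave-one-out evaluation (all strategies, all four
# methods), computed once and shared by the end-to-end tests
defaultEval <- function() cached("defaultEval", {
  cfg <- syntheticConfig()          # the default protocol, seed 42
  ds <- generateDataset(cfg)
  out <- list(cfg = cfg)
  for (strat in c("natural", "momentum_transfer", "quasi_static")) {
    raw <- Filter(function(tr) tr@strategy == strat, ds$trials)
    ntr <- lapply(raw, normalizeTrial)
    names(ntr) <- names(raw)
    nomT <- vapply(Filter(function(tr) tr@trialType == "nominal", raw),
                   function(tr) tr@duration, numeric(1))
    params <- tipmParams(cfg@mass, mean(nomT))
    basins <- lapply(
      c(input_bounds = "input_bounds", lqr = "lqr", fffb = "fffb",
        naive = "naive"),
      function(m) suppressMessages(looBasins(ntr, m, params)))
    out[[strat]] <- list(ntr = ntr, params = params, basins = basins)
  }
  out
})

# classify every trial of the default dataset for one method, optionally
# with dilated basins, reusing the cached leave-one-out basins
defaultOutcomes <- function(method, dilateFactor = 1) {
  ev <- defaultEval()
  res <- list()
  for (strat in c("natural", "momentum_transfer", "quasi_static")) {
    st <- ev[[strat]]
    res[[strat]] <- suppressMessages(
      leaveOneOutEvaluate(st$ntr, method, st$params,
                          dilateFactor = dilateFactor,
                          basins = st$basins[[method]]))
  }
  do.call(rbind, res)
}
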