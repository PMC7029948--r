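#' @include AllClasses.R AllGenerics.R
NULL

.TRIAL_COLS <- c("tau", "r_x", "v_x", "a_x", "r_y", "v_y", "a_y",
                 "d_x", "d_y")

#' Write one trial to CSV with a JSON metadata sidecar
#'
#' The CSV holds the sampled channels (columns `tau, r_x, v_x, a_x, r_y,
#' v_y, a_y, d_x, d_y[, toe_x]`; metres, seconds, newtons); the sidecar
#' `<path>.json` holds subject mass, duration, strategy, trial type,
#' perturbation window and outcome label.
#'
#' @param trial a [StsTrial-class].
#' @param path CSV output path.
#' @return The CSV path, invisibly.
#' @export
writeTrial <- function(trial, path) {
  df <- data.frame(tau = trial@time,
                   r_x = trial@pos[, 1], v_x = trial@vel[, 1],
                   a_x = trial@acc[, 1],
                   r_y = trial@pos[, 2], v_y = trial@vel[, 2],
                   a_y = trial@acc[, 2],
                   d_x = trial@dist[, 1], d_y = trial@dist[, 2])
  if (length(trial@toeX) > 0) df$toe_x <- trial@toeX
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(subject_mass = trial@subjectMass, T = trial@duration,
               strategy = trial@strategy, trial_type = trial@trialType,
               pert_onset = if (length(trial@pertWindow) == 2)
                 trial@pertWindow[1] else NULL,
               pert_offset = if (length(trial@pertWindow) == 2)
                 trial@pertWindow[2] else NULL,
               label = trial@label)
  .writeJson(meta, paste0(path, ".json"))
  invisible(path)
}

#' Read one trial from CSV + JSON sidecar
#'
#' @param path the CSV path written by [writeTrial()].
#' @return A [StsTrial-class].
#' @export
readTrial <- function(path) {
  df <- utils::read.csv(path)
  missing <- setdiff(.TRIAL_COLS, names(df))
  if (length(missing) > 0)
    stop("readTrial: ", path, " is missing required columns: ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  win <- if (!is.null(meta$pert_onset))
    c(meta$pert_onset, meta$pert_offset) else numeric(0)
  new("StsTrial",
      time = df$tau,
      pos = cbind(df$r_x, df$r_y), vel = cbind(df$v_x, df$v_y),
      acc = cbind(df$a_x, df$a_y), dist = cbind(df$d_x, df$d_y),
      toeX = if ("toe_x" %in% names(df)) df$toe_x else numeric(0),
      duration = meta$T, strategy = meta$strategy,
      trialType = meta$trial_type, pertWindow = win,
      label = if (is.null(meta$label)) "unknown" else meta$label,
      subjectMass = meta$subject_mass)
}

#' Read every trial in a directory
#'
#' @param dir directory containing `*.csv` files written by [writeTrial()].
#' @return A named list of [StsTrial-class] objects.
#' @export
readTrialDir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (length(files) == 0) stop("readTrialDir: no trial CSVs in ", dir)
  out <- lapply(files, readTrial)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

# canonical JSON: sorted keys, full precision, no auto-simplification quirks
.writeJson <- function(x, path) {
  txt <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                          pretty = TRUE)
  writeLines(txt, path)
  invisible(path)
}

#' Serialise a zonotope to JSON
#'
#' Format: `{dim, center, generators}` with generators as a list of columns.
#'
#' @param Z a [Zonotope-class].
#' @param path output path; if `NULL`, the JSON string is returned.
#' @return The path (or JSON string), invisibly.
#' @export
zonotopeToJson <- function(Z, path = NULL) {
  obj <- list(dim = length(Z@center), center = Z@center,
              generators = if (ncol(Z@generators) > 0)
                lapply(seq_len(ncol(Z@generators)),
                       function(j) Z@generators[, j]) else list())
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  .writeJson(obj, path)
}

#' Deserialise a zonotope from JSON
#'
#' @param path path to, or string of, JSON written by [zonotopeToJson()].
#' @return A [Zonotope-class].
#' @export
zonotopeFromJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  G <- if (length(obj$generators) > 0) {
    do.call(cbind, if (is.matrix(obj$generators))
      lapply(seq_len(nrow(obj$generators)), function(i) obj$generators[i, ])
      else obj$generators)
  } else NULL
  Zonotope(obj$center, G)
}

#' Serialise a Stability Basin to JSON
#'
#' @param basin a [StabilityBasin-class].
#' @param path output path.
#' @return The path, invisibly.
#' @export
basinToJson <- function(basin, path) {
  ser <- function(z) list(center = z@center,
                          generators = if (ncol(z@generators) > 0)
                            lapply(seq_len(ncol(z@generators)),
                                   function(j) z@generators[, j]) else list())
  obj <- list(controller_type = basin@controllerType, dt = basin@dt,
              max_generators = basin@maxGenerators,
              dilation = basin@dilation,
              params = list(mass = basin@params@mass, g = basin@params@g,
                            Tbar = basin@params@Tbar),
              target = ser(basin@target),
              slices = lapply(basin@slices, ser))
  .writeJson(obj, path)
}

#' Deserialise a Stability Basin from JSON
#'
#' @param path path to JSON written by [basinToJson()].
#' @return A [StabilityBasin-class].
#' @export
basinFromJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  des <- function(z) Zonotope(unlist(z$center),
                              if (length(z$generators) > 0)
                                do.call(cbind, lapply(z$generators, unlist))
                              else NULL)
  new("StabilityBasin",
      slices = lapply(obj$slices, des), target = des(obj$target),
      controllerType = obj$controller_type,
      params = tipmParams(obj$params$mass, obj$params$Tbar),
      dt = obj$dt, maxGenerators = obj$max_generators,
      dilation = obj$dilation)
}

#' Serialise a fitted controller to JSON
#'
#' @param ctrl a controller object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
controllerToJson <- function(ctrl, path) {
  base <- list(strategy = ctrl@strategy, t_grid = ctrl@tGrid)
  karr <- function(K) lapply(seq_len(dim(K)[3]), function(k) K[, , k])
  obj <- if (is(ctrl, "LqrController")) {
    c(base, list(type = "lqr", Q = diag(ctrl@Q), R = diag(ctrl@R),
                 K = karr(ctrl@K), x_bar = ctrl@avg@xBar,
                 u_ol = ctrl@avg@uOl))
  } else if (is(ctrl, "FfFbController")) {
    c(base, list(type = "fffb", ff = ctrl@ff, K = karr(ctrl@K)))
  } else if (is(ctrl, "InputBoundsController")) {
    c(base, list(type = "input_bounds", b_lb = ctrl@bLb, b_ub = ctrl@bUb,
                 K = karr(ctrl@K)))
  } else stop("controllerToJson: unknown controller class ", class(ctrl))
  .writeJson(obj, path)
}

#' Deserialise a controller from JSON
#'
#' @param path path to JSON written by [controllerToJson()].
#' @return A controller object.
#' @export
controllerFromJson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  asMat <- function(x) do.call(rbind, lapply(x, unlist))
  tg <- unlist(obj$t_grid)
  K <- array(NA_real_, c(2, 4, length(tg)))
  for (k in seq_along(tg)) K[, , k] <- asMat(obj$K[[k]])
  if (obj$type == "lqr") {
    new("LqrController", tGrid = tg, strategy = obj$strategy,
        Q = diag(unlist(obj$Q)), R = diag(unlist(obj$R)), K = K,
        avg = new("AvgNominal", tGrid = tg, xBar = asMat(obj$x_bar),
                  uOl = asMat(obj$u_ol)))
  } else if (obj$type == "fffb") {
    new("FfFbController", tGrid = tg, strategy = obj$strategy,
        ff = asMat(obj$ff), K = K)
  } else if (obj$type == "input_bounds") {
    new("InputBoundsController", tGrid = tg, strategy = obj$strategy,
        bLb = asMat(obj$b_lb), bUb = asMat(obj$b_ub), K = K)
  } else stop("controllerFromJson: unknown type ", obj$type)
}

#' Write a reproducibility manifest
#'
#' Records the run configuration, seed and package version so any output
#' table can be regenerated from the raw trial files.
#'
#' @param config a named list of run settings.
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeManifest <- function(config, path) {
  obj <- list(package = "StabilityBasin",
              version = as.character(utils::packageVersion("StabilityBasin")),
              r_version = R.version.string,
              config = config[order(names(config))])
  .writeJson(obj, path)
}
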