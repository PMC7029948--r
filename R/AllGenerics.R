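#' @include AllClasses.R
NULL

#' Apply a linear map to a set
#'
#' For a zonotope, \eqn{M Z = (M c, M G)}: zonotopes are closed under linear
#' maps.
#'
#' @param M a numeric matrix whose column count equals the set dimension.
#' @param Z a [Zonotope-class].
#' @return The mapped [Zonotope-class].
#' @export
setGeneric("linearMap", function(M, Z) standardGeneric("linearMap"))

#' Minkowski sum of two sets
#'
#' For zonotopes, \eqn{Z_1 \oplus Z_2 = (c_1 + c_2, [G_1\; G_2])}.
#'
#' @param Z1,Z2 [Zonotope-class] objects of equal dimension.
#' @return The sum as a [Zonotope-class].
#' @export
setGeneric("minkowskiSum", function(Z1, Z2) standardGeneric("minkowskiSum"))

#' Point containment test via linear programming
#'
#' Finds the representation \eqn{x - c = G\beta} with the smallest maximum
#' absolute coefficient \eqn{\beta_{max}} by solving the linear program
#' \eqn{\min \beta_{max}} s.t. \eqn{G\beta = x - c}, \eqn{|\beta| \le
#' \beta_{max}}. The point is inside iff \eqn{\beta_{max} \le 1} (up to
#' `tol`). If \eqn{x - c} is not in the column space of G the point cannot be
#' represented at all and `betaMax` is `Inf`.
#'
#' @param Z a [Zonotope-class].
#' @param x numeric point of matching dimension.
#' @param tol relative boundary tolerance (default 1e-9).
#' @param exact if `TRUE` (default) always solve the LP so `betaMax` is
#'   exact. If `FALSE`, certified bounds (a feasible representation for the
#'   upper bound, support-function evaluations for the lower bound) may
#'   short-circuit the LP; the inside/outside decision is still exact, but
#'   `betaMax` is then only a certified bound on the true coefficient.
#' @return A list with `inside` (logical), `betaMax` (numeric) and `beta`
#'   (the coefficient vector, `NULL` when short-circuited).
#' @export
setGeneric("containsPoint",
  function(Z, x, tol = 1e-9, exact = TRUE) standardGeneric("containsPoint"))

#' Reduce the number of generators of a zonotope
#'
#' Box-based order reduction: the generators with the smallest
#' \eqn{\|g\|_1 - \|g\|_\infty} score are replaced by their interval hull
#' (one axis-aligned generator per dimension), so the result is an outer
#' approximation of the input.
#'
#' @param Z a [Zonotope-class].
#' @param maxGenerators the generator cap; must be at least the dimension.
#' @return A [Zonotope-class] with at most `maxGenerators` generators that
#'   contains `Z`.
#' @export
setGeneric("reduceOrder",
  function(Z, maxGenerators) standardGeneric("reduceOrder"))

#' Dilate a zonotope about its centre
#'
#' Multiplies every generator by `factor`, leaving the centre unchanged.
#'
#' @param Z a [Zonotope-class] or [StabilityBasin-class].
#' @param factor positive scale factor.
#' @return The dilated object.
#' @export
setGeneric("dilate", function(Z, factor) standardGeneric("dilate"))

#' Support function of a set
#'
#' \eqn{h_Z(d) = \max_{z \in Z} d^\top z}; for a zonotope this is
#' \eqn{d^\top c + \sum_j |d^\top g_j|} in closed form.
#'
#' @param Z a [Zonotope-class].
#' @param d direction vector.
#' @return The support value (numeric scalar).
#' @export
setGeneric("supportFn", function(Z, d) standardGeneric("supportFn"))

#' Evaluate a controller model at a time and state
#'
#' Gains stored on the 201-point grid are linearly interpolated. The LQR and
#' feed-forward-plus-feedback models return a single 2-vector input; the
#' input-bounds model returns the input interval as a 2 x 2 matrix with rows
#' `lb` and `ub`.
#'
#' @param ctrl a controller object.
#' @param t normalised time in \eqn{[0, 1]}.
#' @param x 4-vector model state.
#' @return A 2-vector input, or a 2 x 2 matrix of interval endpoints for the
#'   input-bounds controller.
#' @export
setGeneric("evalController",
  function(ctrl, t, x) standardGeneric("evalController"))

#' Closed-loop dynamics of the model under a controller
#'
#' Substituting a controller into the time-normalised point-mass dynamics
#' gives \eqn{\dot x \in A_{cl}(t) x \oplus W(t)} with
#' \eqn{A_{cl} = A - B K(t)} and an affine input-effect set W that is a
#' singleton for the single-valued controllers and a two-generator zonotope
#' (the image of the input box) for the input-bounds controller. The gravity
#' offset \eqn{(0, 0, 0, -g \bar T^2)} is folded into W.
#'
#' @param ctrl a controller object.
#' @param t normalised time.
#' @param params a [TipmParams-class].
#' @return A list with `Acl` (4 x 4 matrix) and `W` (a [Zonotope-class] in
#'   state-derivative space).
#' @export
setGeneric("closedLoopSystem",
  function(ctrl, t, params) standardGeneric("closedLoopSystem"))

#' Number of generators of a zonotope
#' @param Z a [Zonotope-class].
#' @return Integer generator count.
#' @export
setGeneric("nGenerators", function(Z) standardGeneric("nGenerators"))

#' @describeIn Zonotope-class accessor for the centre.
#' @param Z a [Zonotope-class].
#' @export
setGeneric("center", function(Z) standardGeneric("center"))

#' @describeIn Zonotope-class accessor for the generator matrix.
#' @export
setGeneric("generators", function(Z) standardGeneric("generators"))

#' Slices of a Stability Basin
#' @param basin a [StabilityBasin-class].
#' @return The list of per-time [Zonotope-class] slices (t = 0 to 1).
#' @export
setGeneric("basinSlices", function(basin) standardGeneric("basinSlices"))

#' Slice of a Stability Basin at a normalised time
#' @param basin a [StabilityBasin-class].
#' @param t normalised time in \eqn{[0, 1]}.
#' @return The [Zonotope-class] slice covering `t`.
#' @export
setGeneric("basinSlice", function(basin, t) standardGeneric("basinSlice"))
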