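#' @include AllClasses.R AllGenerics.R
NULL

setMethod("nGenerators", "Zonotope", function(Z) ncol(Z@generators))
setMethod("center", "Zonotope", function(Z) Z@center)
setMethod("generators", "Zonotope", function(Z) Z@generators)

setMethod("linearMap", signature("matrix", "Zonotope"), function(M, Z) {
  if (ncol(M) != length(Z@center))
    stop("linearMap: matrix has ", ncol(M), " columns but the zonotope is ",
         length(Z@center), "-dimensional")
  Zonotope(as.vector(M %*% Z@center), M %*% Z@generators)
})

setMethod("minkowskiSum", signature("Zonotope", "Zonotope"), function(Z1, Z2) {
  if (length(Z1@center) != length(Z2@center))
    stop("minkowskiSum: dimension mismatch (", length(Z1@center), " vs ",
         length(Z2@center), ")")
  Zonotope(Z1@center + Z2@center, cbind(Z1@generators, Z2@generators))
})

setMethod("supportFn", signature("Zonotope", "numeric"), function(Z, d) {
  sum(d * Z@center) + sum(abs(drop(crossprod(Z@generators, d))))
})

setMethod("dilate", signature("Zonotope", "numeric"), function(Z, factor) {
  if (factor <= 0) stop("dilate: factor must be positive")
  Zonotope(Z@center, factor * Z@generators)
})

setMethod("containsPoint", signature("Zonotope", "numeric"),
  function(Z, x, tol = 1e-9, exact = TRUE) {
    if (length(x) != length(Z@center))
      stop("containsPoint: point dimension mismatch")
    y <- x - Z@center
    G <- Z@generators
    p <- ncol(G)
    ynorm <- sqrt(sum(y^2))
    if (p == 0) { # singleton
      bm <- if (ynorm <= tol * (1 + ynorm)) 0 else Inf
      return(list(inside = is.finite(bm), betaMax = bm, beta = numeric(0)))
    }
    # row equilibration: strongly expanded slices mix generator rows of
    # wildly different magnitude; scaling row i of [G | y] leaves beta
    # unchanged but keeps the rank test and the LP well conditioned
    rs <- pmax(apply(abs(G), 1, max), abs(y))
    rs[rs < 1e-300] <- 1
    G <- G / rs
    y <- y / rs
    ynorm <- sqrt(sum(y^2))
    # column-space residual test (robust to rank-deficient G)
    sv <- svd(G)
    pos <- sv$d > max(sv$d[1], 1) * 1e-12
    resid <- y - sv$u[, pos, drop = FALSE] %*%
      drop(crossprod(sv$u[, pos, drop = FALSE], y))
    if (sqrt(sum(resid^2)) > tol * (1 + ynorm))
      return(list(inside = FALSE, betaMax = Inf, beta = NULL))
    # unique-representation fast path: full column rank
    if (sum(pos) == p) {
      beta <- drop(sv$v[, pos, drop = FALSE] %*%
                     (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos]))
      bm <- max(abs(beta), 0)
      return(list(inside = bm <= 1 + tol, betaMax = bm, beta = beta))
    }
    if (!exact) {
      # certified upper bound: the minimum-norm representation is feasible
      beta_ls <- drop(sv$v[, pos, drop = FALSE] %*%
                        (crossprod(sv$u[, pos, drop = FALSE], y) / sv$d[pos]))
      ub <- max(abs(beta_ls))
      if (ub <= 1 - tol)
        return(list(inside = TRUE, betaMax = ub, beta = beta_ls))
      # certified lower bound: beta_max >= d'y / sum_j |d'g_j| for any d
      dirs <- cbind(diag(length(y)), y / max(ynorm, 1e-300))
      denom <- colSums(abs(crossprod(G, dirs)))
      num <- abs(drop(crossprod(dirs, y)))
      lb <- suppressWarnings(max(num[denom > 0] / denom[denom > 0], 0))
      if (lb > 1 + tol)
        return(list(inside = FALSE, betaMax = lb, beta = NULL))
    }
    res <- .zn_beta_lp(G, y)
    if (res$status != 0) {
      if (res$status == 1)
        return(list(inside = FALSE, betaMax = Inf, beta = NULL))
      stop("containsPoint: LP solver failed with status ", res$status)
    }
    list(inside = res$beta_max <= 1 + tol, betaMax = res$beta_max,
         beta = as.numeric(res$beta))
  })

setMethod("reduceOrder", signature("Zonotope", "numeric"),
  function(Z, maxGenerators) {
    n <- length(Z@center)
    if (maxGenerators < n)
      stop("reduceOrder: cap (", maxGenerators,
           ") must be at least the dimension (", n, ")")
    G <- Z@generators
    # zero generators carry no information
    nz <- colSums(abs(G)) > 0
    G <- G[, nz, drop = FALSE]
    p <- ncol(G)
    if (p <= maxGenerators) return(Zonotope(Z@center, G))
    score <- colSums(abs(G)) - apply(abs(G), 2, max)
    keep_n <- maxGenerators - n
    ord <- order(score, decreasing = TRUE)
    keep <- ord[seq_len(keep_n)]
    boxed <- setdiff(ord, keep)
    hull <- diag(rowSums(abs(G[, boxed, drop = FALSE])), n)
    Zonotope(Z@center, cbind(G[, keep, drop = FALSE], hull))
  })

#' Fit an oriented-box zonotope around a point cloud
#'
#' Builds a zonotope that encloses all input points: the generator directions
#' are the left singular vectors of the mean-centred point matrix (the
#' principal axes of the cloud), the extent along each direction is the
#' half-range of the point projections expanded by `expansion` (default 5\%,
#' so that observed points do not lie exactly on the boundary), and the
#' centre is the midpoint of the projection ranges. Used both to build the
#' target set from final states and, per time step, for the naive basin.
#'
#' @param points numeric matrix, one point per row.
#' @param nGenerators number of generator directions to keep (default 4; at
#'   most the point dimension).
#' @param expansion fractional expansion of each generator (default 0.05).
#' @return A [Zonotope-class] containing every input point.
#' @examples
#' pts <- rbind(c(0, 0), c(2, 0), c(0, 1), c(2, 1))
#' fitZonotope(pts)  # the rectangle, scaled 1.05 about its centre
#' @export
fitZonotope <- function(points, nGenerators = 4, expansion = 0.05) {
  P <- as.matrix(points)
  if (nrow(P) < 1) stop("fitZonotope: empty point list")
  d <- ncol(P)
  if (nrow(P) == 1)
    return(Zonotope(as.numeric(P[1, ]), matrix(0, d, min(nGenerators, d))))
  Xc <- sweep(P, 2, colMeans(P))
  sv <- svd(t(Xc), nu = d)
  U <- sv$u
  if (ncol(U) < d) { # complete to an orthonormal basis
    U <- qr.Q(qr(cbind(U, diag(d))))[, seq_len(d), drop = FALSE]
  }
  # deterministic sign convention: first nonzero component positive
  for (j in seq_len(d)) {
    v <- U[, j]
    k <- which(abs(v) > 1e-12)[1]
    if (!is.na(k) && v[k] < 0) U[, j] <- -v
  }
  keep <- seq_len(min(nGenerators, d))
  proj <- P %*% U
  lo <- apply(proj, 2, min)
  hi <- apply(proj, 2, max)
  mid <- (lo + hi) / 2
  half <- (hi - lo) / 2 * (1 + expansion)
  ctr <- as.vector(U %*% mid)
  G <- U[, keep, drop = FALSE] %*% diag(half[keep], length(keep))
  Z <- Zonotope(ctr, G)
  # hard post-condition: dropped directions must carry no extent
  if (length(keep) < d && any(half[-keep] > 1e-9 * max(half, 1)))
    stop("fitZonotope: points extend beyond the ", length(keep),
         " requested generator directions; increase nGenerators")
  chk <- vapply(seq_len(nrow(P)), function(i)
    containsPoint(Z, P[i, ], tol = 1e-7)$inside, logical(1))
  if (!all(chk))
    stop("fitZonotope: internal error, fitted set does not contain all points")
  Z
}

#' Sample points from a zonotope
#'
#' Draws points \eqn{c + G\beta} with \eqn{\beta} uniform on \eqn{[-1,1]^p};
#' used by the sampling oracles in the test suite.
#'
#' @param Z a [Zonotope-class].
#' @param n number of points.
#' @param boundary if `TRUE`, draw \eqn{\beta} from the vertices
#'   \eqn{\{-1,1\}^p} instead (extreme points of the coefficient box).
#' @return An n x dim matrix of points.
#' @export
sampleZonotope <- function(Z, n, boundary = FALSE) {
  p <- ncol(Z@generators)
  B <- if (boundary) {
    matrix(sample(c(-1, 1), n * p, replace = TRUE), p, n)
  } else {
    matrix(stats::runif(n * p, -1, 1), p, n)
  }
  t(Z@center + Z@generators %*% B)
}
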