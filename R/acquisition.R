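# Pareto bookkeeping and acquisition mathematics: nondominated sorting,
# 2-d hypervolume, the psi helper, exact two-objective EHVI, the
# sequence-similarity penalty alpha, and the iteration-dependent fitness.

#' Nondominated subset of a 2-objective point set
#'
#' Both objectives are maximized (here \eqn{-\tilde B_2} and \eqn{\tilde D}).
#' Points tied on both coordinates keep the first-seen representative.
#'
#' @param points matrix or data.frame with two objective columns.
#' @return integer indices (into the rows of \code{points}) of the
#'   nondominated set, ordered by increasing first objective.
#' @export
pareto_front <- function(points) {
  pts <- as.matrix(points)
  stopifnot(ncol(pts) == 2, all(is.finite(pts)))
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  # sort by obj1 desc, obj2 desc, original index asc; sweep keeps points with
  # a running-max second objective
  o <- order(-pts[, 1], -pts[, 2], seq_len(n))
  keep <- logical(n)
  best2 <- -Inf
  for (i in o) {
    if (pts[i, 2] > best2) {
      keep[i] <- TRUE
      best2 <- pts[i, 2]
    }
    # ties on both coordinates: the sort puts the smaller original index
    # first, so the first-seen duplicate is the one kept
  }
  idx <- which(keep)
  idx[order(pts[idx, 1])]
}

#' Dominated hypervolume of a 2-objective front
#'
#' Area of the union of rectangles spanned by the front points above a
#' reference point (both objectives maximized), by sort-and-sweep. Points that
#' do not dominate the reference point are excluded with a warning.
#'
#' @param front matrix with two objective columns (need not be nondominated;
#'   the nondominated subset is used).
#' @param reference length-2 reference point.
#' @return nonnegative area.
#' @export
hypervolume <- function(front, reference) {
  pts <- as.matrix(front)
  if (nrow(pts) == 0) return(0)
  ok <- pts[, 1] > reference[1] & pts[, 2] > reference[2]
  if (any(!ok)) {
    warning(sum(!ok), " point(s) do not dominate the reference; excluded")
    pts <- pts[ok, , drop = FALSE]
  }
  if (nrow(pts) == 0) return(0)
  idx <- pareto_front(pts)
  pts <- pts[idx, , drop = FALSE]   # obj1 ascending, obj2 descending
  a <- pts[, 1]; b <- pts[, 2]
  n <- length(a)
  lo <- c(reference[1], a[-n])
  sum((a - lo) * (b - reference[2]))
}

#' The Psi helper of the EHVI integrand
#'
#' Closed form of
#' \eqn{\Psi(a,b,\mu,\sigma) = \int_{-\infty}^{b} (a-z)\,
#' \mathcal{N}(z;\mu,\sigma)\,dz
#' = (a-\mu)\Phi\left(\frac{b-\mu}{\sigma}\right)
#' + \sigma\,\phi\left(\frac{b-\mu}{\sigma}\right)}.
#' For \eqn{\sigma \to 0} the step-function limit
#' \eqn{(a-\mu)\,1\{\mu \le b\}} is used.
#'
#' @param a,b,mu,sigma scalar arguments (sigma >= 0).
#' @return value of the integral.
#' @export
psi <- function(a, b, mu, sigma) {
  if (sigma <= 0) return(if (mu <= b) a - mu else 0)
  z <- (b - mu) / sigma
  (a - mu) * pnorm(z) + sigma * dnorm(z)
}

#' Exact expected hypervolume improvement for two objectives
#'
#' EHVI of a candidate with independent Gaussian objective predictions over a
#' nondominated front (both objectives maximized). Computed by the exact
#' strip decomposition over the augmented front (sentinel endpoints at the
#' reference coordinates), which is guaranteed nonnegative and reduces to the
#' deterministic hypervolume improvement as both prediction sds tend to zero.
#'
#' @param pred_b2 list or data.frame row with \code{mean}, \code{sd}:
#'   prediction for the first objective (\eqn{-\tilde B_2}).
#' @param pred_d prediction for the second objective (\eqn{\tilde D}).
#' @param front matrix of nondominated points (two columns, same orientation).
#' @param reference length-2 reference point.
#' @return nonnegative EHVI value.
#' @export
ehvi <- function(pred_b2, pred_d, front, reference) {
  ehvi_batch(pred_b2$mean, pred_b2$sd, pred_d$mean, pred_d$sd,
             front, reference)
}

#' Vectorized exact EHVI
#'
#' @param mu1,sd1 first-objective predictions (vectors).
#' @param mu2,sd2 second-objective predictions.
#' @param front nondominated matrix (two columns).
#' @param reference length-2 reference point.
#' @return numeric vector of EHVI values.
#' @export
ehvi_batch <- function(mu1, sd1, mu2, sd2, front, reference) {
  pts <- as.matrix(front)
  stopifnot(nrow(pts) >= 1)
  idx <- pareto_front(pts)
  pts <- pts[idx, , drop = FALSE]
  cpp_ehvi_batch(as.numeric(mu1), pmax(as.numeric(sd1), 0),
                 as.numeric(mu2), pmax(as.numeric(sd2), 0),
                 pts[, 1], pts[, 2], reference[1], reference[2])
}

#' Similarity penalty against previously proposed sequences
#'
#' \eqn{\alpha} is the harmonic mean of the cosine dissimilarities
#' \eqn{d_k = \tfrac12 (1 - \cos(x, x_k))} between the candidate and the
#' history of previously simulated or proposed feature vectors:
#' \eqn{\alpha = [\frac{1}{J}\sum_k d_k^{-1}]^{-1}}. It is 1 for an empty
#' history and tends to 0 as the candidate approaches any single history
#' entry.
#'
#' @param candidate feature vector (length 30) or matrix of candidates.
#' @param history matrix of history feature vectors (rows), possibly empty.
#' @return numeric vector of penalties in [0, 1].
#' @export
similarity_penalty <- function(candidate, history) {
  if (is.null(dim(candidate))) candidate <- matrix(candidate, nrow = 1)
  if (is.null(history) || NROW(history) == 0) {
    return(rep(1, nrow(candidate)))
  }
  history <- as.matrix(history)
  cn <- sqrt(rowSums(candidate^2))
  hn <- sqrt(rowSums(history^2))
  if (any(cn == 0) || any(hn == 0)) stop("zero-norm feature vector")
  cosm <- (candidate %*% t(history)) / outer(cn, hn)
  d <- pmin(pmax((1 - cosm) / 2, 0), 1)
  apply(d, 1, function(dk) {
    if (any(dk == 0)) return(0)
    1 / mean(1 / dk)
  })
}

#' Iteration-dependent design fitness
#'
#' Builds the batched fitness function for stage \eqn{k} of the design
#' schedule: stage 0 maximizes \eqn{-\tilde B_2} alone; stages
#' \eqn{0 < k < k_{final}} maximize EHVI gated by the phase classifier label
#' and damped by the similarity penalty; the final stage maximizes the pure
#' exploitation objective \eqn{-\tilde B_2 + \tilde D}.
#'
#' @param k iteration index.
#' @param k_final index of the exploitation round (default 8).
#' @param b2_model fitted \code{b2_surrogate}.
#' @param d_model fitted \code{d_surrogate} (required for k >= 1).
#' @param classifier fitted \code{phase_classifier} (required for
#'   0 < k < k_final).
#' @param front standardized nondominated front matrix (\eqn{-\tilde B_2},
#'   \eqn{\tilde D}).
#' @param reference EHVI reference point in the standardized plane.
#' @param history_env environment with element \code{H}, the feature-vector
#'   history matrix for the similarity penalty (grown as children are
#'   accepted); \code{NULL} disables the penalty.
#' @return function mapping a feature matrix to a fitness vector.
#' @export
make_fitness <- function(k, k_final = 8, b2_model, d_model = NULL,
                         classifier = NULL, front = NULL, reference = NULL,
                         history_env = NULL) {
  if (k == 0) {
    return(function(X) -.gp_mu(b2_model, X))
  }
  if (k >= k_final) {
    if (is.null(d_model)) stop("exploitation stage requires the D surrogate")
    return(function(X) -.gp_mu(b2_model, X) + .gp_mu(d_model, X))
  }
  if (is.null(d_model) || is.null(classifier) || is.null(front) ||
      is.null(reference)) {
    stop("EHVI stage requires D surrogate, classifier, front and reference")
  }
  pts <- as.matrix(front)
  pts <- pts[pareto_front(pts), , drop = FALSE]
  fa <- pts[, 1]; fb <- pts[, 2]
  fl <- classifier$flat
  function(X) {
    pb <- .gp_mu_sd(b2_model, X)
    pd <- .gp_mu_sd(d_model, X)
    e <- cpp_ehvi_batch(-pb$mu, pb$sd, pd$mu, pd$sd, fa, fb,
                        reference[1], reference[2])
    lab <- as.numeric(cpp_forest_score(X, fl$offset, fl$leftd, fl$rightd,
                                       fl$splitvar, fl$splitval,
                                       fl$pred) >= 0.5)
    a <- if (is.null(history_env)) 1 else .alpha_fast(X, history_env)
    e * lab * a
  }
}

# similarity penalty with cached history norms; the environment holds H
# (feature rows) and hn (their Euclidean norms)
.alpha_fast <- function(X, env) {
  if (is.null(env$H) || nrow(env$H) == 0) return(rep(1, nrow(X)))
  if (is.null(env$hn) || length(env$hn) != nrow(env$H)) {
    env$hn <- sqrt(rowSums(env$H^2))
  }
  cosm <- tcrossprod(X, env$H) / outer(sqrt(rowSums(X^2)), env$hn)
  d <- pmin(pmax((1 - cosm) / 2, 0), 1)
  nr <- nrow(d)
  out <- numeric(nr)
  for (i in seq_len(nr)) {
    dk <- d[i, ]
    out[i] <- if (any(dk == 0)) 0 else 1 / mean(1 / dk)
  }
  out
}
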