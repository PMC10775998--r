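# Surrogate property models: standardization transform, Gaussian-process
# regressors for the standardized objectives, and a random-forest
# phase-separation classifier (with a flattened-forest export used by the
# genetic-algorithm inner loop).

#' Standard-normal transformation of a property
#'
#' Zero-mean, unit-sd transform fitted on the current dataset; the fitted
#' scale is kept with every model so predictions can be mapped back.
#'
#' @param values numeric vector (at least two distinct values).
#' @return list with \code{values} (standardized) and \code{scale} (class
#'   \code{std_scale}: \code{mean}, \code{sd}).
#' @export
standardize <- function(values) {
  stopifnot(length(values) >= 2)
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("constant input cannot be standardized")
  sc <- structure(list(mean = mean(values), sd = s), class = "std_scale")
  list(values = (values - sc$mean) / sc$sd, scale = sc)
}

#' Apply / invert a fitted standardization
#' @param scale a \code{std_scale}.
#' @param x values on the original (or standardized, for the inverse) scale.
#' @return transformed values.
#' @export
std_transform <- function(scale, x) (x - scale$mean) / scale$sd

#' @rdname std_transform
#' @export
std_inverse <- function(scale, x) x * scale$sd + scale$mean

# ---- Gaussian-process regression --------------------------------------------
# Squared-exponential kernel on the unit-scaled feature cube, isotropic
# length scale, fitted observation noise. Hyperparameters (log length scale,
# log signal sd, log noise sd) maximize the log marginal likelihood.

gp_kernel <- function(X1, X2, ell, sf2) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  sf2 * exp(-d2 / (2 * ell^2))
}

#' Fit a Gaussian-process regressor
#'
#' @param X numeric matrix of unit-scaled feature rows.
#' @param y numeric response (typically standardized).
#' @param noise_sd fixed observation-noise sd, or \code{NULL} to fit it.
#' @param min_rows smallest accepted training set.
#' @param maxit optimizer iterations for the marginal-likelihood search.
#' @return object of class \code{idp_gpr}.
#' @export
gpr_fit <- function(X, y, noise_sd = NULL, min_rows = 5, maxit = 80) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < min_rows) stop("need at least ", min_rows, " training rows")
  stopifnot(length(y) == n)
  med_d <- median(dist(X[sample.int(n, min(n, 200)), , drop = FALSE]))
  if (!is.finite(med_d) || med_d <= 0) med_d <- 1
  nll <- function(theta) {
    ell <- exp(theta[1]); sf2 <- exp(2 * theta[2])
    sn2 <- if (is.null(noise_sd)) exp(2 * theta[3]) else noise_sd^2
    K <- gp_kernel(X, X, ell, sf2)
    diag(K) <- diag(K) + sn2 + 1e-8
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  init <- c(log(med_d), log(max(sd(y), 1e-3)),
            if (is.null(noise_sd)) log(max(sd(y) * 0.1, 1e-3)))
  opt <- optim(init, nll, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-7))
  theta <- opt$par
  ell <- exp(theta[1]); sf2 <- exp(2 * theta[2])
  sn2 <- if (is.null(noise_sd)) exp(2 * theta[3]) else noise_sd^2
  K <- gp_kernel(X, X, ell, sf2)
  diag(K) <- diag(K) + sn2 + 1e-8
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  structure(list(X = X, alpha = alpha, L = L, LT = t(L),
                 norm2 = rowSums(X^2), ell = ell, sf2 = sf2,
                 sn2 = sn2, nll = opt$value),
            class = "idp_gpr")
}

# lean prediction paths used in the GA inner loop (no data.frame overhead)
.gp_cross_kernel <- function(gp, X) {
  d2 <- outer(rowSums(X^2), gp$norm2, "+") - 2 * tcrossprod(X, gp$X)
  d2[d2 < 0] <- 0
  gp$sf2 * exp(-d2 / (2 * gp$ell^2))
}

.gp_mu <- function(model, X) {
  gp <- model$gp
  as.numeric(.gp_cross_kernel(gp, X) %*% gp$alpha)
}

.gp_mu_sd <- function(model, X) {
  gp <- model$gp
  Ks <- .gp_cross_kernel(gp, X)
  V <- forwardsolve(gp$LT, t(Ks))
  list(mu = as.numeric(Ks %*% gp$alpha),
       sd = sqrt(pmax(gp$sf2 - colSums(V^2), 0)))
}

#' Predict with a Gaussian-process regressor
#'
#' @param object an \code{idp_gpr}.
#' @param Xnew matrix (or single vector) of feature rows.
#' @param ... unused.
#' @return data.frame with \code{mean} and \code{sd} (latent-function
#'   predictive sd; reverts to the prior sd far from the data).
#' @export
predict.idp_gpr <- function(object, Xnew, ...) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  p <- .gp_mu_sd(list(gp = object), Xnew)
  data.frame(mean = p$mu, sd = p$sd)
}

#' Fit the B2 surrogate (GPR on standardized B2)
#'
#' @param X unit-scaled feature matrix.
#' @param B2 measured second virial coefficients (raw units).
#' @param ... passed to \code{\link{gpr_fit}}.
#' @return list of class \code{b2_surrogate} with the GP and the fitted
#'   standardization scale.
#' @export
fit_b2_gpr <- function(X, B2, ...) {
  st <- standardize(B2)
  structure(list(gp = gpr_fit(X, st$values, ...), scale = st$scale),
            class = c("b2_surrogate", "property_surrogate"))
}

#' Fit the D surrogate (GPR on standardized D, phase separators only)
#'
#' The regression runs on the standardized linear D scale by default; an
#' optional log-space mode regresses standardized \eqn{\log D} instead
#' (diffusivities are strictly positive, and the transform is monotone so
#' Pareto dominance in the standardized plane is unaffected).
#'
#' @param X unit-scaled feature matrix of phase-separating sequences.
#' @param D their condensed-phase self-diffusion coefficients.
#' @param log_space regress on log(D) (default FALSE; monotone option).
#' @param ... passed to \code{\link{gpr_fit}}.
#' @return list of class \code{d_surrogate}.
#' @export
fit_d_gpr <- function(X, D, log_space = FALSE, ...) {
  if (log_space) stopifnot(all(D > 0))
  st <- standardize(if (log_space) log(D) else D)
  structure(list(gp = gpr_fit(X, st$values, ...), scale = st$scale,
                 log_space = log_space),
            class = c("d_surrogate", "property_surrogate"))
}

#' Predict a standardized property with its uncertainty
#' @param object a \code{property_surrogate}.
#' @param Xnew feature rows.
#' @param ... unused.
#' @return data.frame with standardized \code{mean} and \code{sd}.
#' @export
predict.property_surrogate <- function(object, Xnew, ...) {
  predict(object$gp, Xnew)
}

# ---- Random-forest phase classifier -----------------------------------------

#' Fit the phase-separation classifier
#'
#' Random forest on the unit-scaled features with binary labels (TRUE =
#' phase-separating). The fitted forest is additionally flattened to plain
#' arrays so the genetic-algorithm inner loop can evaluate it without R
#' dispatch overhead.
#'
#' @param X unit-scaled feature matrix.
#' @param labels logical (or 0/1) vector, both classes present.
#' @param ntree number of trees (default 500).
#' @param seed RNG seed for the forest.
#' @return object of class \code{phase_classifier}.
#' @export
fit_phase_classifier <- function(X, labels, ntree = 500, seed = 1) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("single-class input; need both classes")
  X <- as.matrix(X)
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  set.seed(seed)
  rf <- randomForest::randomForest(x = X, y = factor(labels,
                                                     levels = c(FALSE, TRUE)),
                                   ntree = ntree)
  structure(list(rf = rf, flat = flatten_forest(rf), ntree = ntree),
            class = "phase_classifier")
}

# Export a randomForest classification forest to concatenated arrays for the
# C++ evaluator.
flatten_forest <- function(rf) {
  ntree <- rf$ntree
  trees <- lapply(seq_len(ntree), function(k)
    randomForest::getTree(rf, k, labelVar = FALSE))
  sizes <- vapply(trees, nrow, integer(1))
  offset <- c(0L, cumsum(sizes))[seq_len(ntree)]
  all <- do.call(rbind, trees)
  list(offset = as.integer(offset),
       leftd = as.integer(all[, 1]),
       rightd = as.integer(all[, 2]),
       splitvar = as.integer(all[, 3]),
       splitval = as.numeric(all[, 4]),
       pred = as.integer(all[, 6]))
}

#' Predict phase separation
#'
#' @param object a \code{phase_classifier}.
#' @param Xnew feature rows.
#' @param ... unused.
#' @return data.frame with hard 0/1 \code{label} and vote-fraction
#'   \code{score}.
#' @export
predict.phase_classifier <- function(object, Xnew, ...) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  fl <- object$flat
  score <- cpp_forest_score(as.matrix(Xnew), fl$offset, fl$leftd, fl$rightd,
                            fl$splitvar, fl$splitval, fl$pred)
  data.frame(label = as.integer(score >= 0.5), score = score)
}

#' Save / load a surrogate model bundle
#'
#' The bundle keeps the models together with the scaler configuration,
#' standardization scales, seed and package version so that predictions are
#' reproducible on reload.
#'
#' @param bundle list of fitted models plus metadata.
#' @param path file path (.rds).
#' @return \code{load_model_bundle} returns the bundle.
#' @export
save_model_bundle <- function(bundle, path) {
  bundle$idpal_version <- as.character(utils::packageVersion("idpal"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) readRDS(path)
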