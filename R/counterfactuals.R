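# Post-hoc counterfactual analysis of a converged run: selection of
# near-miss sequences for each Pareto-optimal sequence, average feature
# differences, and pairwise similarity matrices of the Pareto set.

#' Select counterfactual sequences for a Pareto-optimal sequence
#'
#' A dataset sequence is a counterfactual of a Pareto-optimal sequence when
#' (i) the cosine similarity of their full 30-dim feature vectors exceeds
#' \code{sim_threshold} and (ii) its Euclidean distance to the Pareto front
#' in the standard-normalized \eqn{(B_2, D)} plane (z-scored over the
#' phase-separating subset, distance to the nearest front point) lies within
#' \code{dist_range}. The Pareto sequence itself is excluded by the lower
#' distance bound.
#'
#' @param pareto_seq sequence (character) on the front.
#' @param dataset data.frame with columns \code{sequence}, \code{B2},
#'   \code{D}, \code{phase_sep}.
#' @param front_seqs sequences of the full Pareto set (used for the
#'   distance-to-front computation); defaults to \code{pareto_seq} alone.
#' @param params,scaler featurization configuration.
#' @param sim_threshold cosine-similarity gate (default 0.9).
#' @param dist_range dimensionless distance window (default [0.15, 0.3]).
#' @return data.frame of selected counterfactual rows, with added columns
#'   \code{cos_sim} and \code{front_dist}.
#' @export
select_counterfactuals <- function(pareto_seq, dataset, front_seqs = NULL,
                                   params = load_parameter_table(),
                                   scaler = default_scaler_config(params),
                                   sim_threshold = 0.9,
                                   dist_range = c(0.15, 0.3)) {
  keep <- dataset$phase_sep & !is.na(dataset$B2) & !is.na(dataset$D)
  ds <- dataset[keep, , drop = FALSE]
  if (nrow(ds) == 0) stop("empty dataset (no phase-separating records)")
  if (is.null(front_seqs)) front_seqs <- pareto_seq
  zb <- standardize(ds$B2); zd <- standardize(ds$D)
  zmat <- cbind(zb$values, zd$values)
  fidx <- match(front_seqs, ds$sequence)
  if (any(is.na(fidx))) stop("front sequence(s) missing from the dataset")
  fz <- zmat[fidx, , drop = FALSE]
  d2f <- apply(zmat, 1, function(p)
    sqrt(min(colSums((t(fz) - p)^2))))
  fx <- feature_vector(pareto_seq, params, scaler)
  X <- feature_matrix(ds$sequence, params, scaler, warn_clamp = FALSE)
  cs <- as.numeric((X %*% fx) / (sqrt(rowSums(X^2)) * sqrt(sum(fx^2))))
  sel <- cs > sim_threshold & d2f >= dist_range[1] & d2f <= dist_range[2]
  out <- ds[sel, , drop = FALSE]
  out$cos_sim <- cs[sel]
  out$front_dist <- d2f[sel]
  out
}

#' Average feature differences between a Pareto sequence and its
#' counterfactuals
#'
#' For each of the 30 features, the mean over counterfactuals of
#' \eqn{x_k(\mathcal{P}) - x_k(\mathcal{C}_j)}, with standard errors of the
#' mean.
#'
#' @param pareto_seq the Pareto-optimal sequence.
#' @param counterfactuals character vector of counterfactual sequences
#'   (n >= 1).
#' @param params,scaler featurization configuration.
#' @return data.frame with \code{feature}, \code{mean_diff}, \code{se},
#'   \code{n}.
#' @export
avg_feature_differences <- function(pareto_seq, counterfactuals,
                                    params = load_parameter_table(),
                                    scaler = default_scaler_config(params)) {
  n <- length(counterfactuals)
  stopifnot(n >= 1)
  fp <- feature_vector(pareto_seq, params, scaler)
  fc <- feature_matrix(counterfactuals, params, scaler, warn_clamp = FALSE)
  diffs <- sweep(-fc, 2, fp, "+")  # x_k(P) - x_k(C_j), rows j
  se <- if (n > 1) apply(diffs, 2, sd) / sqrt(n) else rep(NA_real_, 30)
  data.frame(feature = colnames(fc), mean_diff = colMeans(diffs),
             se = se, n = n, row.names = NULL)
}

#' Pairwise similarity matrices of a Pareto set
#'
#' Cosine similarities between the composition components and between the
#' sequence-descriptor components of the feature vectors of a sequence set;
#' both matrices are symmetric with unit diagonal. Mean off-diagonal
#' similarities are reported as summaries.
#'
#' @param seqs character vector (>= 2 sequences).
#' @param params,scaler featurization configuration.
#' @return list with \code{composition}, \code{descriptors} (matrices) and
#'   \code{mean_composition}, \code{mean_descriptors}.
#' @export
similarity_matrices <- function(seqs, params = load_parameter_table(),
                                scaler = default_scaler_config(params)) {
  stopifnot(length(seqs) >= 2)
  X <- feature_matrix(seqs, params, scaler, warn_clamp = FALSE)
  cos_mat <- function(M) {
    nn <- sqrt(rowSums(M^2))
    out <- (M %*% t(M)) / outer(nn, nn)
    diag(out) <- 1
    out
  }
  comp <- cos_mat(X[, 1:20, drop = FALSE])
  desc <- cos_mat(X[, 21:30, drop = FALSE])
  off <- upper.tri(comp)
  list(composition = comp, descriptors = desc,
       mean_composition = mean(comp[off]),
       mean_descriptors = mean(desc[off]))
}

#' Full counterfactual report for a converged run
#'
#' Applies \code{\link{select_counterfactuals}} and
#' \code{\link{avg_feature_differences}} to every sequence of the current
#' Pareto archive.
#'
#' @param state an \code{al_state}.
#' @param ... passed to \code{\link{select_counterfactuals}}.
#' @return data.frame stacking per-front-sequence feature differences, with
#'   a \code{pareto_id} column; front sequences without counterfactuals are
#'   reported with \code{n = 0} rows omitted.
#' @export
counterfactual_report <- function(state, ...) {
  arch <- al_archive(state)
  out <- NULL
  for (i in seq_len(nrow(arch$points))) {
    cf <- select_counterfactuals(arch$points$sequence[i], state$data,
                                 front_seqs = arch$points$sequence,
                                 params = state$params,
                                 scaler = state$scaler, ...)
    if (nrow(cf) == 0) next
    ad <- avg_feature_differences(arch$points$sequence[i], cf$sequence,
                                  state$params, state$scaler)
    ad$pareto_id <- arch$points$id[i]
    out <- rbind(out, ad)
  }
  out
}
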