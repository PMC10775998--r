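# 30-dimensional sequence featurization: 20 composition fractions plus 10
# chain-level descriptors (N, mean hydropathy, SHD, charge fractions, net
# charge, SCD, mean-field B2, Shannon entropy, mean residue mass).

DESCRIPTOR_NAMES <- c("N", "lambda_bar", "SHD", "q_plus", "q_minus",
                      "abs_q", "SCD", "B2_MF", "S", "M_bar")

.code_lookup <- local({
  lk <- integer(256)
  lk[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_along(AA_ALPHABET)
  lk
})

#' Validate an amino-acid sequence
#'
#' @param seq character scalar of one-letter codes.
#' @param min_len minimum accepted length (2 outside design contexts).
#' @return the validated, uppercased sequence (invisibly its input form).
#' @export
validate_sequence <- function(seq, min_len = 2) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  codes <- .code_lookup[utf8ToInt(seq)]
  if (any(codes == 0)) {
    bad <- unique(strsplit(seq, "")[[1]][codes == 0])
    stop("invalid character in sequence: ", paste(bad, collapse = ", "))
  }
  if (nchar(seq) < min_len) stop("sequence shorter than ", min_len, " residues")
  seq
}

seq_to_codes <- function(seq) {
  codes <- .code_lookup[utf8ToInt(toupper(seq))]
  if (any(codes == 0)) {
    bad <- unique(strsplit(toupper(seq), "")[[1]][codes == 0])
    stop("invalid character in sequence: ", paste(bad, collapse = ", "))
  }
  codes
}

#' Amino-acid composition vector
#'
#' Fraction of each of the 20 residue types, in fixed alphabetical
#' one-letter-code order (A, C, D, ..., Y). Fractions sum to 1.
#'
#' @param seq character scalar of one-letter codes.
#' @return named numeric vector of length 20.
#' @export
composition_vector <- function(seq) {
  codes <- seq_to_codes(validate_sequence(seq, min_len = 1))
  setNames(tabulate(codes, nbins = 20) / length(codes), AA_ALPHABET)
}

#' Chain-level sequence descriptors
#'
#' Computes the ten descriptors used alongside composition: sequence length
#' \eqn{N}; mean hydropathy \eqn{\bar\lambda}; sequence hydropathy decoration
#' \eqn{SHD = N^{-1}\sum_{m>n}(\lambda_m+\lambda_n)(m-n)^{-\beta}} with
#' \eqn{\beta = 1}; fractions of positive and negative residues; absolute net
#' charge per residue; sequence charge decoration
#' \eqn{SCD = N^{-1}\sum_{m>n} q_m q_n (m-n)^{1/2}}; the mean-field second
#' virial coefficient \eqn{B_2^{MF}} (composition-weighted sum of single-bead
#' pair virial integrals of the CG potential, \eqn{N^2}-weighted, Angstrom^3);
#' Shannon entropy of the composition (nats); and mean residue mass (g/mol).
#'
#' @param seq character scalar (length >= 2).
#' @param params an \code{idp_params} object.
#' @param shd_beta SHD distance-kernel exponent (default 1).
#' @param scd_exp SCD distance-kernel exponent (default 1/2).
#' @return named numeric vector of length 10.
#' @export
descriptors <- function(seq, params = load_parameter_table(),
                        shd_beta = 1, scd_exp = 0.5) {
  seq <- validate_sequence(seq, min_len = 2)
  m <- cpp_seq_features(list(seq_to_codes(seq)), params$residues$lambda,
                        params$residues$charge, params$residues$mass,
                        pair_b2_matrix(params), shd_beta, scd_exp)
  setNames(m[1, 21:30], DESCRIPTOR_NAMES)
}

#' Default fixed-bound scaler for the descriptor block
#'
#' Min-max scaling bounds for the 10 descriptors, fixed (not
#' dataset-dependent) so feature vectors are comparable across active-learning
#' iterations. Length bounds follow the design window [20, 50]; hydropathy and
#' charge fractions live in [0, 1] natively; SHD/SCD/B2_MF bounds are computed
#' from extremal sequences at N = 50 (all-W for SHD, single-charge and diblock
#' polyampholytes for SCD, most attractive/repulsive homopolymers for B2_MF)
#' with a 10% margin on the computed extremes.
#'
#' @param params an \code{idp_params} object.
#' @param n_max design length bound used for the extremal sequences.
#' @return object of class \code{idp_scaler}: list of \code{lo}, \code{hi}
#'   numeric vectors (length 10, descriptor order).
#' @export
default_scaler_config <- function(params = load_parameter_table(), n_max = 50) {
  strrep_seq <- function(ch, n) paste(rep(ch, n), collapse = "")
  half <- n_max %/% 2
  diblock <- paste0(strrep_seq("E", half), strrep_seq("K", n_max - half))
  mono_q <- strrep_seq("E", n_max)
  w_homo <- strrep_seq("W", n_max)
  homos <- vapply(AA_ALPHABET, strrep_seq, "", n = n_max)
  d_homos <- t(vapply(homos, descriptors, numeric(10), params = params))
  shd_max <- max(d_homos[, "SHD"])
  scd_lo <- descriptors(diblock, params)[["SCD"]]
  scd_hi <- descriptors(mono_q, params)[["SCD"]]
  b2mf_lo <- min(d_homos[, "B2_MF"])
  b2mf_hi <- max(d_homos[, "B2_MF"])
  pad <- function(lo, hi) {
    w <- (hi - lo) * 0.1
    c(lo - w, hi + w)
  }
  scd_b <- pad(scd_lo, scd_hi)
  b2_b <- pad(b2mf_lo, b2mf_hi)
  obj <- list(
    lo = setNames(c(20, 0, 0, 0, 0, 0, scd_b[1], b2_b[1], 0,
                    min(params$residues$mass)), DESCRIPTOR_NAMES),
    hi = setNames(c(50, 1, shd_max * 1.1, 1, 1, 1, scd_b[2], b2_b[2], log(20),
                    max(params$residues$mass)), DESCRIPTOR_NAMES))
  class(obj) <- "idp_scaler"
  obj
}

#' Unit-scaled 30-dimensional feature vector
#'
#' Concatenation of the composition vector (natively in [0,1]) and the
#' min-max-scaled descriptors. Descriptors falling outside the configured
#' bounds are clamped to [0,1] with a warning.
#'
#' @param seq character scalar.
#' @param params an \code{idp_params} object.
#' @param scaler an \code{idp_scaler} (default bounds if omitted).
#' @return named numeric vector of length 30, all entries in [0,1].
#' @export
feature_vector <- function(seq, params = load_parameter_table(),
                           scaler = default_scaler_config(params)) {
  feature_matrix(seq, params, scaler)[1, ]
}

#' Feature matrix for a set of sequences
#'
#' @param seqs character vector of sequences.
#' @inheritParams feature_vector
#' @param warn_clamp warn when a descriptor is clamped to its bounds.
#' @return numeric matrix, one row per sequence, 30 named columns.
#' @export
feature_matrix <- function(seqs, params = load_parameter_table(),
                           scaler = default_scaler_config(params),
                           warn_clamp = TRUE) {
  codes <- lapply(seqs, seq_to_codes)
  raw <- cpp_seq_features(codes, params$residues$lambda, params$residues$charge,
                          params$residues$mass, pair_b2_matrix(params), 1, 0.5)
  d <- raw[, 21:30, drop = FALSE]
  scl <- sweep(sweep(d, 2, scaler$lo, "-"), 2, scaler$hi - scaler$lo, "/")
  if (any(scl < 0 | scl > 1)) {
    # warn only for genuine violations, not floating-point dust at a bound
    if (warn_clamp && any(scl < -1e-9 | scl > 1 + 1e-9)) {
      warning("descriptor outside scaler bounds; clamped to [0,1]")
    }
    scl[scl < 0] <- 0
    scl[scl > 1] <- 1
  }
  out <- cbind(raw[, 1:20, drop = FALSE], scl)
  colnames(out) <- c(paste0("comp_", AA_ALPHABET), DESCRIPTOR_NAMES)
  rownames(out) <- names(seqs)
  out
}

#' Cosine similarity between feature vectors
#'
#' Standard cosine on the full 30-dim vector or on the composition
#' (columns 1-20) or descriptor (columns 21-30) sub-vector, matching the
#' composition/descriptor similarity decomposition used to compare
#' Pareto-optimal sequences.
#'
#' @param x,y feature vectors (length 30, same scaling config).
#' @param part one of \code{"full"}, \code{"composition"},
#'   \code{"descriptors"}.
#' @return value in [-1, 1].
#' @export
cosine_similarity <- function(x, y, part = c("full", "composition",
                                             "descriptors")) {
  part <- match.arg(part)
  idx <- switch(part, full = 1:30, composition = 1:20, descriptors = 21:30)
  if (length(x) == length(y) && length(x) < 30) idx <- seq_along(x)
  xs <- x[idx]; ys <- y[idx]
  nx <- sqrt(sum(xs^2)); ny <- sqrt(sum(ys^2))
  if (nx == 0 || ny == 0) stop("zero-norm sub-vector in cosine similarity")
  sum(xs * ys) / (nx * ny)
}
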