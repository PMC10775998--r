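# Synthetic property oracle with a planted Pareto front, plus sequence-set
# generators (disorder-biased random sequences, the 80-homopolymer grid, and
# a structured reference family whose brute-force front defines the planted
# front for closed-loop recovery tests).

#' Synthetic-oracle configuration
#'
#' The toy oracle maps three chain descriptors to ground-truth properties
#' through an attraction score
#' \deqn{a = \min(1, (w_h \bar\lambda + w_u u + w_s s)/a_{norm})}
#' with \eqn{u = (N-20)/30} the scaled chain length and
#' \eqn{s = \min(1, \max(0, -SCD)/s_0)} the scaled polyampholyte charge
#' patterning (negative SCD marks blocky arrangements of opposite charges;
#' like-charge chains have positive SCD and earn no patterning bonus). Then
#' \eqn{B_2^{true}/V_0 = b_{off} - b_{amp} a^2} (hydrophobicity, length and
#' blocky charge patterning all deepen the attraction), phase separation iff
#' \eqn{B_2^{true}/V_0 < -b_{thresh}}, and for separators
#' \eqn{D^{true}/D_0 = k_D (V_0 / -B_2^{true}) \sqrt{50/N} (1 + \gamma s)}:
#' the homopolymer Rouse law \eqn{D \propto (-N^{1/2} B_2)^{-1}} times a
#' patterning bonus that plants a heteropolymer advantage over homopolymers
#' of equal \eqn{B_2}. Condensed density \eqn{\rho_c = 0.3 + 0.7 a} g/ml.
#' Measurement noise: Gaussian on \eqn{B_2} (sd \code{noise_b2} in V0 units)
#' and multiplicative lognormal on \eqn{D} (sd \code{noise_d_rel}).
#'
#' @param w_h,w_u,w_s descriptor weights of the attraction score.
#' @param a_norm normalization of the attraction score.
#' @param s0 negative-SCD magnitude mapped to full patterning (s = 1).
#' @param b_off,b_amp offset and amplitude of \eqn{B_2^{true}/V_0}.
#' @param b_thresh phase threshold on \eqn{-B_2^{true}/V_0}.
#' @param k_d,gamma diffusion prefactor and patterning-bonus strength.
#' @param noise_b2 sd of B2 noise in units of V0.
#' @param noise_d_rel relative sd of D noise.
#' @return object of class \code{oracle_config}.
#' @export
oracle_config <- function(w_h = 0.45, w_u = 0.35, w_s = 0.4, a_norm = 0.9,
                          s0 = 2.5, b_off = 10, b_amp = 60, b_thresh = 10,
                          k_d = 5, gamma = 1.5, noise_b2 = 0.5,
                          noise_d_rel = 0.05) {
  stopifnot(noise_b2 >= 0, noise_d_rel >= 0, b_amp > 0, s0 > 0)
  structure(list(w_h = w_h, w_u = w_u, w_s = w_s, a_norm = a_norm, s0 = s0,
                 b_off = b_off, b_amp = b_amp, b_thresh = b_thresh,
                 k_d = k_d, gamma = gamma, noise_b2 = noise_b2,
                 noise_d_rel = noise_d_rel),
            class = "oracle_config")
}

# noise-free ground truth for a descriptor matrix (rows: N, lambda_bar, SCD)
oracle_truth <- function(N, lambda_bar, SCD, cfg, ref = reference_scales(50)) {
  u <- (N - 20) / 30
  s <- pmin(1, pmax(0, -SCD) / cfg$s0)
  a <- pmin(1, (cfg$w_h * lambda_bar + cfg$w_u * u + cfg$w_s * s) / cfg$a_norm)
  b2v0 <- cfg$b_off - cfg$b_amp * a^2
  phase <- b2v0 < -cfg$b_thresh
  dd0 <- ifelse(phase,
                cfg$k_d * (1 / (-b2v0)) * sqrt(50 / N) * (1 + cfg$gamma * s),
                NA_real_)
  rho <- ifelse(phase, 0.3 + 0.7 * a, NA_real_)
  data.frame(B2 = b2v0 * ref$V0, phase_sep = phase, rho_c = rho,
             D = dd0 * ref$D0)
}

#' Evaluate sequences with the synthetic property oracle
#'
#' Returns one property record per sequence in the standard schema:
#' \code{id, B2, B2_se, phase_sep, rho_c, rho_c_se, D, D_se, provenance}.
#' The phase flag is determined by the noise-free ground truth; \code{D} and
#' \code{rho_c} are present iff the sequence phase separates.
#'
#' @param seqs character vector of sequences (named or not).
#' @param cfg an \code{oracle_config}.
#' @param params an \code{idp_params}.
#' @param seed RNG seed for the measurement noise (\code{NULL} = noise-free).
#' @return data.frame of property records.
#' @export
toy_oracle <- function(seqs, cfg = oracle_config(),
                       params = load_parameter_table(), seed = NULL) {
  ref <- reference_scales(50, params = params)
  desc <- t(vapply(seqs, function(s) {
    d <- descriptors(s, params)
    c(d[["N"]], d[["lambda_bar"]], d[["SCD"]])
  }, numeric(3)))
  truth <- oracle_truth(desc[, 1], desc[, 2], desc[, 3], cfg, ref)
  n <- length(seqs)
  b2_se <- rep(cfg$noise_b2 * ref$V0, n)
  d_se <- ifelse(truth$phase_sep, cfg$noise_d_rel * truth$D, NA_real_)
  if (!is.null(seed)) {
    set.seed(seed)
    truth$B2 <- truth$B2 + rnorm(n, sd = cfg$noise_b2 * ref$V0)
    truth$D <- truth$D * exp(rnorm(n, sd = cfg$noise_d_rel))
    truth$rho_c <- truth$rho_c + rnorm(n, sd = 0.01)
  }
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  data.frame(id = ids, sequence = unname(seqs),
             B2 = truth$B2, B2_se = b2_se,
             phase_sep = truth$phase_sep,
             rho_c = truth$rho_c, rho_c_se = ifelse(truth$phase_sep, 0.01, NA),
             D = ifelse(truth$phase_sep, truth$D, NA_real_), D_se = d_se,
             provenance = "oracle", row.names = NULL)
}

#' Disorder-biased random sequences
#'
#' Random polypeptides emulating short curated disordered regions: lengths
#' uniform over \code{length_range}, residues drawn from a composition
#' profile with modest enrichment of G, S, P, E, K and Q over a flat
#' background.
#'
#' @param n number of sequences.
#' @param length_range inclusive length bounds (default [20, 50]).
#' @param composition_profile named nonnegative weights over the 20 residues.
#' @param seed RNG seed.
#' @return named character vector of sequences.
#' @export
generate_disprot_like <- function(n, length_range = c(20, 50),
                                  composition_profile = NULL, seed = 1) {
  stopifnot(n >= 1)
  if (is.null(composition_profile)) {
    composition_profile <- setNames(rep(1, 20), AA_ALPHABET)
    composition_profile[c("G", "S", "P", "E", "K", "Q")] <- 2.5
  }
  if (any(composition_profile < 0) || sum(composition_profile) <= 0) {
    stop("invalid composition profile (negative or zero weights)")
  }
  prof <- composition_profile[AA_ALPHABET]
  prof <- prof / sum(prof)
  set.seed(seed)
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = prof), collapse = ""),
    "")
  setNames(seqs, sprintf("dis%04d", seq_len(n)))
}

#' The 80-homopolymer suite
#'
#' All 20 amino-acid homopolymers at chain lengths 20, 30, 40 and 50.
#'
#' @return named character vector of 80 sequences (names like \code{Y40}).
#' @export
homopolymer_suite <- function() {
  grid <- expand.grid(aa = AA_ALPHABET, N = c(20, 30, 40, 50),
                      stringsAsFactors = FALSE)
  setNames(vapply(seq_len(nrow(grid)),
                  function(i) strrep(grid$aa[i], grid$N[i]), ""),
           paste0(grid$aa, grid$N))
}

#' Structured reference family for the planted front
#'
#' Diblock polyampholyte head plus hydrophobic tail:
#' \eqn{E^c K^c W^w G^{N-2c-w}} over a grid of lengths \eqn{N}, charge-block
#' sizes \eqn{c} and tryptophan counts \eqn{w}. The family spans the
#' hydrophobicity, length and charge-patterning extremes of the oracle's
#' descriptor space, so its brute-force nondominated set serves as the
#' planted Pareto front in closed-loop recovery tests.
#'
#' @param lengths chain lengths (default seq(20, 50, 5)).
#' @param block_sizes per-sign charge-block sizes (default 0, 2, ..., 10).
#' @param w_step step of the tryptophan-count grid.
#' @return named character vector of sequences.
#' @export
reference_family <- function(lengths = seq(20, 50, by = 5),
                             block_sizes = seq(0, 10, by = 2), w_step = 2) {
  out <- character(0)
  for (N in lengths) {
    for (cc in block_sizes[2 * block_sizes <= N]) {
      for (w in seq(0, N - 2 * cc, by = w_step)) {
        seq_ <- paste0(strrep("E", cc), strrep("K", cc), strrep("W", w),
                       strrep("G", N - 2 * cc - w))
        out[sprintf("fam_N%d_c%d_w%d", N, cc, w)] <- seq_
      }
    }
  }
  out
}

#' Planted Pareto front of the synthetic oracle
#'
#' Noise-free oracle evaluation of the reference family, brute-force
#' nondominated extraction in the \eqn{(-B_2/V_0, D/D_0)} plane, and the
#' dominated hypervolume with respect to \code{reference} (default: the
#' phase threshold on the first axis, zero on the second).
#'
#' @param cfg an \code{oracle_config}.
#' @param params an \code{idp_params}.
#' @param family sequences to enumerate (default \code{reference_family()}).
#' @param reference hypervolume reference point.
#' @return list with \code{points} (data.frame id, sequence, nB2_V0, D_D0),
#'   \code{hypervolume}, \code{reference}.
#' @export
planted_front <- function(cfg = oracle_config(),
                          params = load_parameter_table(),
                          family = reference_family(),
                          reference = NULL) {
  ref <- reference_scales(50, params = params)
  if (is.null(reference)) reference <- c(cfg$b_thresh, 0)
  rec <- toy_oracle(family, cfg, params, seed = NULL)
  rec <- rec[rec$phase_sep, , drop = FALSE]
  obj <- cbind(nB2_V0 = -rec$B2 / ref$V0, D_D0 = rec$D / ref$D0)
  idx <- pareto_front(obj)
  pts <- data.frame(id = rec$id[idx], sequence = rec$sequence[idx],
                    nB2_V0 = obj[idx, 1], D_D0 = obj[idx, 2])
  list(points = pts,
       hypervolume = hypervolume(obj[idx, , drop = FALSE], reference),
       reference = reference)
}
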