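# The active-learning outer loop: seed round, EHVI rounds, final
# exploitation round; oracle evaluation, surrogate refits, Pareto archive
# maintenance and convergence metrics.

#' Active-learning configuration
#'
#' @param n_iterations total design iterations (default 9: the B2-only seed
#'   round k = 0, seven EHVI rounds, and a final exploitation round).
#' @param ga a \code{\link{ga_config}}.
#' @param ref_point hypervolume reference point in the raw dimensionless
#'   \eqn{(-B_2/V_0, D/D_0)} plane used for convergence metrics.
#' @param regime_split \eqn{-B_2/V_0} threshold for the per-regime
#'   convergence metrics (default 50).
#' @param ehvi_ref_margin margin (fraction of the observed range) by which
#'   the per-iteration standardized EHVI reference point is pushed below the
#'   observed minima.
#' @param min_separators separators required before the D surrogate and
#'   classifier are fitted (otherwise the B2-only stage repeats).
#' @param ntree classifier trees.
#' @param gp_maxit marginal-likelihood optimizer iterations.
#' @param max_parents cap on the parent pool per iteration.
#' @param d_log_space regress the D surrogate on log(D) and standardize the
#'   EHVI objective in that space (monotone, so dominance is unchanged).
#' @return object of class \code{al_config}.
#' @export
al_config <- function(n_iterations = 9, ga = ga_config(),
                      ref_point = c(10, 0), regime_split = 50,
                      ehvi_ref_margin = 0.1, min_separators = 5,
                      ntree = 500, gp_maxit = 80, max_parents = 32,
                      d_log_space = FALSE) {
  stopifnot(n_iterations >= 2)
  structure(list(n_iterations = n_iterations, ga = ga, ref_point = ref_point,
                 regime_split = regime_split,
                 ehvi_ref_margin = ehvi_ref_margin,
                 min_separators = min_separators, ntree = ntree,
                 gp_maxit = gp_maxit, max_parents = max_parents,
                 d_log_space = d_log_space),
            class = "al_config")
}

#' Initialize an active-learning state from seed data
#'
#' Evaluates the seed sequences through the oracle and builds the initial
#' state: dataset, feature matrix, empty convergence history, iteration
#' index 0.
#'
#' @param seed_seqs named character vector of seed sequences.
#' @param oracle property oracle: function(seqs, seed) returning the standard
#'   property record data.frame (see \code{\link{toy_oracle}}).
#' @param cfg an \code{al_config}.
#' @param params an \code{idp_params}.
#' @param scaler an \code{idp_scaler}.
#' @param master_seed master RNG seed governing the whole run.
#' @return object of class \code{al_state}.
#' @export
al_init <- function(seed_seqs, oracle, cfg = al_config(),
                    params = load_parameter_table(),
                    scaler = default_scaler_config(params), master_seed = 1) {
  set.seed(master_seed)
  iter_seeds <- matrix(sample.int(.Machine$integer.max - 1,
                                  2 * (cfg$n_iterations + 1)),
                       ncol = 2)
  rec <- oracle(seed_seqs, iter_seeds[1, 1])
  feats <- feature_matrix(rec$sequence, params, scaler, warn_clamp = FALSE)
  ref <- reference_scales(50, params = params)
  state <- structure(list(k = 0, data = rec, features = feats,
                          cfg = cfg, params = params, scaler = scaler,
                          oracle = oracle, ref = ref,
                          iter_seeds = iter_seeds, master_seed = master_seed,
                          history = NULL, models = NULL),
                     class = "al_state")
  state
}

#' @export
print.al_state <- function(x, ...) {
  cat(sprintf("active-learning state: iteration %d, %d sequences (%d phase-separating), front size %d\n",
              x$k, nrow(x$data), sum(x$data$phase_sep),
              nrow(al_archive(x)$points)))
  invisible(x)
}

# raw-plane objectives of the phase-separating subset
.al_objectives <- function(state) {
  sep <- which(state$data$phase_sep & !is.na(state$data$D))
  obj <- cbind(nB2_V0 = -state$data$B2[sep] / state$ref$V0,
               D_D0 = state$data$D[sep] / state$ref$D0)
  list(idx = sep, obj = obj)
}

#' Current Pareto archive
#'
#' Nondominated set of the phase-separating dataset in the raw dimensionless
#' \eqn{(-B_2/V_0, D/D_0)} plane, with its hypervolume relative to the
#' configured reference point.
#'
#' @param state an \code{al_state}.
#' @return list with \code{points} (data.frame), \code{hypervolume},
#'   \code{reference}.
#' @export
al_archive <- function(state) {
  oo <- .al_objectives(state)
  if (length(oo$idx) == 0) {
    return(list(points = data.frame(id = character(0), sequence = character(0),
                                    nB2_V0 = numeric(0), D_D0 = numeric(0)),
                hypervolume = 0, reference = state$cfg$ref_point))
  }
  idx <- pareto_front(oo$obj)
  rows <- oo$idx[idx]
  dom <- oo$obj[idx, 1] > state$cfg$ref_point[1] &
    oo$obj[idx, 2] > state$cfg$ref_point[2]
  hv <- if (any(dom)) {
    hypervolume(oo$obj[idx[dom], , drop = FALSE], state$cfg$ref_point)
  } else 0
  list(points = data.frame(id = state$data$id[rows],
                           sequence = state$data$sequence[rows],
                           nB2_V0 = oo$obj[idx, 1], D_D0 = oo$obj[idx, 2]),
       hypervolume = hv, reference = state$cfg$ref_point)
}

# fit the surrogate models for the current dataset; returns NULL components
# when prerequisites are not met
.al_fit_models <- function(state) {
  cfg <- state$cfg
  X <- state$features
  b2_model <- fit_b2_gpr(X, state$data$B2, maxit = cfg$gp_maxit)
  sep <- state$data$phase_sep
  d_model <- classifier <- NULL
  if (sum(sep) >= cfg$min_separators) {
    d_model <- fit_d_gpr(X[sep, , drop = FALSE], state$data$D[sep],
                         log_space = isTRUE(cfg$d_log_space),
                         maxit = cfg$gp_maxit)
    if (any(!sep)) {
      classifier <- fit_phase_classifier(X, sep, ntree = cfg$ntree,
                                         seed = state$iter_seeds[state$k + 1, 2])
    }
  }
  list(b2 = b2_model, d = d_model, classifier = classifier)
}

#' Run one active-learning iteration
#'
#' Refits the surrogates, proposes a batch of children with the stage-k
#' fitness (k = 0: minimize predicted \eqn{\tilde B_2}; intermediate rounds:
#' EHVI gated by the phase classifier and damped by the similarity penalty;
#' final round: maximize \eqn{-\tilde B_2 + \tilde D}), evaluates the
#' children through the oracle, appends the results and updates the
#' convergence history. If too few phase separators exist for the D
#' surrogate, the B2-only stage repeats regardless of k.
#'
#' @param state an \code{al_state}.
#' @return the updated state (iteration index advanced).
#' @export
run_iteration <- function(state) {
  cfg <- state$cfg
  k <- state$k
  k_final <- cfg$n_iterations - 1
  seeds <- state$iter_seeds[k + 2, ]
  models <- .al_fit_models(state)
  have_d <- !is.null(models$d) && !is.null(models$classifier)
  stage <- if (k == 0 || !have_d) "b2" else if (k >= k_final) "exploit" else "ehvi"

  # standardized objective plane for EHVI
  history_env <- NULL
  front_std <- NULL; ehvi_ref <- NULL
  if (stage == "ehvi") {
    sep <- state$data$phase_sep
    stB2 <- standardize(state$data$B2)
    d_obs <- state$data$D[sep]
    stD <- standardize(if (isTRUE(cfg$d_log_space)) log(d_obs) else d_obs)
    obj_std <- cbind(-stB2$values[sep], stD$values)
    front_std <- obj_std[pareto_front(obj_std), , drop = FALSE]
    rng1 <- range(obj_std[, 1]); rng2 <- range(obj_std[, 2])
    ehvi_ref <- c(rng1[1] - cfg$ehvi_ref_margin * max(diff(rng1), 1e-6),
                  rng2[1] - cfg$ehvi_ref_margin * max(diff(rng2), 1e-6))
    # similarity-penalty history: all previously simulated sequences plus
    # the candidates already accepted in the current iteration
    history_env <- new.env(parent = emptyenv())
    history_env$H <- state$features
  }

  fitness_X <- switch(stage,
    b2 = make_fitness(0, b2_model = models$b2),
    ehvi = make_fitness(k, k_final = k_final, b2_model = models$b2,
                        d_model = models$d, classifier = models$classifier,
                        front = front_std, reference = ehvi_ref,
                        history_env = history_env),
    exploit = make_fitness(k_final, k_final = k_final, b2_model = models$b2,
                           d_model = models$d))
  params <- state$params; scaler <- state$scaler
  # codes-accepting fitness with a precomputed featurization context (the GA
  # engine works on integer-coded sequences)
  b2p <- pair_b2_matrix(params)
  lam <- params$residues$lambda; chg <- params$residues$charge
  mss <- params$residues$mass
  lo <- scaler$lo; iw <- 1 / (scaler$hi - scaler$lo)
  featurize_codes <- function(codes) {
    raw <- cpp_seq_features(codes, lam, chg, mss, b2p, 1, 0.5)
    d <- raw[, 21:30, drop = FALSE]
    scl <- (d - matrix(lo, nrow(d), 10, byrow = TRUE)) *
      matrix(iw, nrow(d), 10, byrow = TRUE)
    scl[scl < 0] <- 0; scl[scl > 1] <- 1
    cbind(raw[, 1:20, drop = FALSE], scl)
  }
  fitness_fn <- function(codes) fitness_X(featurize_codes(codes))
  attr(fitness_fn, "accepts_codes") <- TRUE

  # parent pool: stage 0 uses the most attractive (lowest-B2) sequences,
  # later stages the current Pareto set (supplemented from the lowest-B2
  # pool when the front is small)
  if (stage == "b2") {
    neg <- which(state$data$B2 < 0)
    if (length(neg) == 0) neg <- order(state$data$B2)[seq_len(min(8, nrow(state$data)))]
    ord <- neg[order(state$data$B2[neg])]
    parents <- state$data$sequence[head(ord, cfg$max_parents)]
  } else {
    arch <- al_archive(state)
    parents <- arch$points$sequence
    if (length(parents) < 2) {
      extra <- state$data$sequence[order(state$data$B2)]
      parents <- unique(c(parents, head(extra, 4)))
    }
    if (length(parents) > cfg$max_parents) {
      parents <- parents[seq_len(cfg$max_parents)]
    }
  }

  on_accept <- NULL
  if (!is.null(history_env)) {
    history_env$hn <- sqrt(rowSums(history_env$H^2))
    on_accept <- function(seq_) {
      fv <- featurize_codes(list(seq_to_codes(seq_)))
      history_env$H <- rbind(history_env$H, fv)
      history_env$hn <- c(history_env$hn, sqrt(sum(fv^2)))
    }
  }
  prev_front_ids <- al_archive(state)$points$id
  children <- propose_children(parents, fitness_fn, cfg$ga, seed = seeds[1],
                               forbidden = state$data$sequence,
                               on_accept = on_accept)
  names(children) <- sprintf("it%d_c%02d", k, seq_along(children))

  # exact-duplicate short-circuit: never evaluate a sequence twice
  fresh <- !(children %in% state$data$sequence)
  rec <- state$oracle(children[fresh], seeds[2])
  state$data <- rbind(state$data, rec)
  state$features <- rbind(state$features,
                          feature_matrix(rec$sequence, params, scaler,
                                         warn_clamp = FALSE))
  state$models <- models
  state$k <- k + 1

  arch <- al_archive(state)
  new_ids <- setdiff(arch$points$id, prev_front_ids)
  split <- cfg$regime_split
  in_reg <- arch$points$nB2_V0 <= split
  reg_pts <- arch$points[in_reg, , drop = FALSE]
  reg_dom <- reg_pts$nB2_V0 > cfg$ref_point[1] & reg_pts$D_D0 > cfg$ref_point[2]
  hv_reg <- if (any(reg_dom)) {
    hypervolume(as.matrix(reg_pts[reg_dom, c("nB2_V0", "D_D0")]),
                cfg$ref_point)
  } else 0
  metrics <- data.frame(
    k = k, stage = stage, n_data = nrow(state$data),
    n_separating = sum(state$data$phase_sep),
    n_front = nrow(arch$points),
    hypervolume = arch$hypervolume,
    frac_new_pareto = if (nrow(arch$points) > 0)
      length(new_ids) / nrow(arch$points) else 0,
    n_front_regime = nrow(reg_pts),
    hypervolume_regime = hv_reg,
    frac_new_pareto_regime = if (nrow(reg_pts) > 0)
      length(intersect(new_ids, reg_pts$id)) / nrow(reg_pts) else 0)
  state$history <- rbind(state$history, metrics)
  state
}

#' Run a full active-learning campaign
#'
#' @inheritParams al_init
#' @return the final \code{al_state} after \code{cfg$n_iterations} rounds.
#' @export
run_active_learning <- function(seed_seqs, oracle, cfg = al_config(),
                                params = load_parameter_table(),
                                scaler = default_scaler_config(params),
                                master_seed = 1) {
  state <- al_init(seed_seqs, oracle, cfg, params, scaler, master_seed)
  for (i in seq_len(cfg$n_iterations)) state <- run_iteration(state)
  state
}

#' Convergence metrics of a run
#'
#' Per-iteration hypervolume of the Pareto archive, fraction of newly added
#' Pareto points (relative to the current front size), and the same
#' quantities restricted to the weakly interacting regime
#' \eqn{-B_2/V_0 \le} \code{regime_split}.
#'
#' @param state an \code{al_state} with at least one completed iteration.
#' @return data.frame, one row per iteration.
#' @export
convergence_metrics <- function(state) {
  if (is.null(state$history)) stop("no completed iterations")
  state$history
}

#' Convenience toy-oracle factory
#'
#' Wraps \code{\link{toy_oracle}} into the oracle interface used by the
#' active-learning loop.
#'
#' @param cfg an \code{oracle_config}.
#' @param params an \code{idp_params}.
#' @return function(seqs, seed) -> property records.
#' @export
make_toy_oracle <- function(cfg = oracle_config(),
                            params = load_parameter_table()) {
  function(seqs, seed) toy_oracle(seqs, cfg, params, seed = seed)
}

#' Closed-loop recovery study against the planted front
#'
#' Runs repeated full active-learning campaigns on the synthetic oracle from
#' independently generated disorder-biased seed sets and measures, for each
#' run, the fraction of the planted front's hypervolume attained by the final
#' archive, together with the per-iteration hypervolume and
#' fraction-new-Pareto traces.
#'
#' @param n_runs number of independent campaigns.
#' @param master_seed seed from which all per-run seeds derive.
#' @param n_seed_seqs size of each run's random seed set.
#' @param cfg an \code{al_config} (batch size, schedule).
#' @param oracle_cfg an \code{oracle_config}.
#' @param params,scaler featurization configuration.
#' @return list with \code{recovery} (per-run hypervolume ratios),
#'   \code{hv_traces} and \code{frac_new_traces} (matrices, one row per run),
#'   and \code{planted} (the planted-front summary).
#' @export
closed_loop_recovery <- function(n_runs = 20, master_seed = 1,
                                 n_seed_seqs = 64,
                                 cfg = al_config(ga = ga_config(n_trials = 16,
                                                                n_children = 16)),
                                 oracle_cfg = oracle_config(),
                                 params = load_parameter_table(),
                                 scaler = default_scaler_config(params)) {
  set.seed(master_seed)
  run_seeds <- sample.int(2147483646, 2 * n_runs)
  pf <- planted_front(oracle_cfg, params, reference = cfg$ref_point)
  oracle <- make_toy_oracle(oracle_cfg, params)
  recovery <- numeric(n_runs)
  hv <- fn <- matrix(NA_real_, n_runs, cfg$n_iterations)
  for (i in seq_len(n_runs)) {
    seeds <- generate_disprot_like(n_seed_seqs, seed = run_seeds[2 * i - 1])
    st <- run_active_learning(seeds, oracle, cfg, params, scaler,
                              master_seed = run_seeds[2 * i])
    m <- convergence_metrics(st)
    recovery[i] <- al_archive(st)$hypervolume / pf$hypervolume
    hv[i, ] <- m$hypervolume
    fn[i, ] <- m$frac_new_pareto
  }
  list(recovery = recovery, hv_traces = hv, frac_new_traces = fn,
       planted = pf)
}
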