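# Genetic-algorithm sequence proposal: crossover / mutation / deletion /
# growth moves, the 100-step greedy local search, and the batched
# trials-per-child selection scheme.

#' Genetic-algorithm configuration
#'
#' Defaults follow the design protocol: moves applied independently in the
#' order crossover, mutation, deletion, growth with probabilities 0.5, 0.8,
#' 0.2, 0.5; 100 steps per trial; 96 trials per child; 96 children per
#' iteration; sequence lengths kept in [20, 50].
#'
#' @param p_crossover,p_mutation,p_deletion,p_growth move probabilities.
#' @param n_steps local-search steps per trial.
#' @param n_trials independent trials per child (best-of-trials selection).
#' @param n_children children per iteration.
#' @param len_min,len_max design length bounds.
#' @param dup_retries trial-batch reruns allowed when the best trial result
#'   duplicates an already accepted child.
#' @return object of class \code{ga_config}.
#' @export
ga_config <- function(p_crossover = 0.5, p_mutation = 0.8, p_deletion = 0.2,
                      p_growth = 0.5, n_steps = 100, n_trials = 96,
                      n_children = 96, len_min = 20, len_max = 50,
                      dup_retries = 2) {
  probs <- c(p_crossover, p_mutation, p_deletion, p_growth)
  stopifnot(all(probs >= 0 & probs <= 1), len_min >= 20, len_max <= 50,
            len_min <= len_max, n_steps >= 1, n_trials >= 1, n_children >= 1)
  structure(list(p_crossover = p_crossover, p_mutation = p_mutation,
                 p_deletion = p_deletion, p_growth = p_growth,
                 n_steps = n_steps, n_trials = n_trials,
                 n_children = n_children, len_min = len_min,
                 len_max = len_max, dup_retries = dup_retries),
            class = "ga_config")
}

#' Single-cut crossover of two parent sequences
#'
#' Random cut-and-swap at a shared cut position: the prefix of one parent up
#' to the cut is joined to the suffix of the other beyond it (so crossing a
#' sequence with itself returns the sequence unchanged, and the child length
#' equals the second parent's). A result violating the length bounds is
#' resampled; if no valid cut exists the move is skipped (identity).
#'
#' @param parent_a,parent_b sequences.
#' @param len_min,len_max length bounds.
#' @param max_tries resampling attempts.
#' @return child sequence.
#' @export
crossover <- function(parent_a, parent_b, len_min = 20, len_max = 50,
                      max_tries = 10) {
  na <- nchar(parent_a); nb <- nchar(parent_b)
  if (na < 2 || nb < 2) return(parent_a)
  for (t in seq_len(max_tries)) {
    cut <- sample.int(min(na, nb) - 1, 1)
    child <- paste0(substr(parent_a, 1, cut), substr(parent_b, cut + 1, nb))
    nc <- nchar(child)
    if (nc >= len_min && nc <= len_max) return(child)
  }
  parent_a
}

#' Point mutation
#'
#' Substitutes one uniformly chosen site with a uniformly chosen residue.
#'
#' @param seq sequence.
#' @param n_sub substitutions per move (default 1).
#' @return mutated sequence.
#' @export
mutate <- function(seq, n_sub = 1) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  for (s in seq_len(n_sub)) {
    i <- sample.int(n, 1)
    ch[i] <- AA_ALPHABET[sample.int(20, 1)]
  }
  paste(ch, collapse = "")
}

#' Deletion move
#'
#' Removes a random contiguous segment with length uniform over the feasible
#' lengths; identity when the sequence is already at the lower bound.
#'
#' @param seq sequence.
#' @param len_min lower length bound.
#' @return shortened (or unchanged) sequence.
#' @export
delete_segment <- function(seq, len_min = 20) {
  n <- nchar(seq)
  max_del <- n - len_min
  if (max_del < 1) return(seq)
  len <- sample.int(max_del, 1)
  start <- sample.int(n - len + 1, 1)
  paste0(substr(seq, 1, start - 1), substr(seq, start + len, n))
}

#' Growth move
#'
#' Duplicates a random contiguous segment of the sequence in place (the copy
#' is inserted immediately after the original segment), with segment length
#' uniform over the feasible lengths; identity at the upper bound.
#'
#' @param seq sequence.
#' @param len_max upper length bound.
#' @return lengthened (or unchanged) sequence.
#' @export
grow_segment <- function(seq, len_max = 50) {
  n <- nchar(seq)
  max_grow <- min(len_max - n, n)
  if (max_grow < 1) return(seq)
  len <- sample.int(max_grow, 1)
  start <- sample.int(n - len + 1, 1)
  seg <- substr(seq, start, start + len - 1)
  paste0(substr(seq, 1, start + len - 1), seg, substr(seq, start + len, n))
}

# one GA proposal: the four moves in fixed order with their probabilities
ga_propose <- function(current, parents, cfg) {
  child <- current
  if (runif(1) < cfg$p_crossover) {
    partner <- parents[sample.int(length(parents), 1)]
    child <- crossover(child, partner, cfg$len_min, cfg$len_max)
  }
  if (runif(1) < cfg$p_mutation) child <- mutate(child)
  if (runif(1) < cfg$p_deletion) child <- delete_segment(child, cfg$len_min)
  if (runif(1) < cfg$p_growth) child <- grow_segment(child, cfg$len_max)
  child
}

#' Single-trial greedy sequence optimization
#'
#' Starts from a random parent and applies the four moves for
#' \code{cfg$n_steps} steps with greedy keep-if-better acceptance (ties
#' accepted with probability 1/2 so flat fitness landscapes still explore).
#' Returns the best sequence encountered.
#'
#' @param parents parent pool (character vector).
#' @param fitness_fn batched fitness: function(character vector) -> numeric.
#' @param cfg a \code{ga_config}.
#' @param seed optional RNG seed.
#' @return list with \code{sequence}, \code{fitness}, and the best-so-far
#'   \code{trace}.
#' @export
optimize_one <- function(parents, fitness_fn, cfg = ga_config(), seed = NULL) {
  stopifnot(length(parents) >= 1)
  if (!is.null(seed)) set.seed(seed)
  current <- parents[sample.int(length(parents), 1)]
  f_cur <- fitness_fn(current)[1]
  best <- current; f_best <- f_cur
  trace <- numeric(cfg$n_steps)
  for (s in seq_len(cfg$n_steps)) {
    cand <- ga_propose(current, parents, cfg)
    f_cand <- fitness_fn(cand)[1]
    if (f_cand > f_cur || (f_cand == f_cur && runif(1) < 0.5)) {
      current <- cand; f_cur <- f_cand
    }
    if (f_cur >= f_best) {   # ties keep the most recent state (exploration)
      best <- current; f_best <- f_cur
    }
    trace[s] <- f_best
  }
  list(sequence = best, fitness = f_best, trace = trace)
}

#' Propose a batch of unique children
#'
#' For each child, \code{cfg$n_trials} independent greedy searches are run
#' (batched: one fitness call evaluates all trials' proposals per step) and
#' the best-fitness trial result is taken. If the winner duplicates an
#' already accepted child the trial batch is rerun up to
#' \code{cfg$dup_retries} times, then the best non-duplicate trial result is
#' used; if none exists the batch is returned partial with a warning.
#' Accepted children are reported through \code{on_accept} as they are chosen
#' (this is how the similarity-penalty history grows within an iteration).
#'
#' @param parents parent pool.
#' @param fitness_fn batched fitness: function(character vector) -> numeric.
#' @param cfg a \code{ga_config}.
#' @param seed master seed; per-child/trial streams are derived from it.
#' @param forbidden sequences that must not be emitted again (e.g. the
#'   dataset).
#' @param on_accept optional callback invoked with each accepted child.
#' @return character vector of unique child sequences (length
#'   \code{cfg$n_children} unless uniqueness was unreachable).
#' @export
propose_children <- function(parents, fitness_fn, cfg = ga_config(),
                             seed = 1, forbidden = character(0),
                             on_accept = NULL) {
  stopifnot(length(parents) >= 1)
  set.seed(seed)
  parent_codes <- lapply(parents, seq_to_codes)
  accepts_codes <- isTRUE(attr(fitness_fn, "accepts_codes"))
  eval_fit <- if (accepts_codes) fitness_fn else {
    function(codes) fitness_fn(codes_to_strings(codes))
  }
  children <- character(0)
  for (ci in seq_len(cfg$n_children)) {
    got <- NULL
    for (try in 0:cfg$dup_retries) {
      res <- run_trial_batch(parent_codes, eval_fit, cfg)
      seqs <- codes_to_strings(res$codes)
      o <- order(-res$fitness)
      win <- seqs[o[1]]
      if (!(win %in% c(children, forbidden))) {
        got <- win
        break
      }
      # best trial result is a duplicate: fall back to the best fresh one
      fresh <- o[!(seqs[o] %in% c(children, forbidden))]
      if (length(fresh) > 0 && try == cfg$dup_retries) {
        got <- seqs[fresh[1]]
        break
      }
    }
    if (is.null(got)) {
      warning("uniqueness unreachable after retries; returning partial batch ",
              "of ", length(children), " children")
      break
    }
    children <- c(children, got)
    if (!is.null(on_accept)) on_accept(got)
  }
  children
}

# one batch of cfg$n_trials greedy searches on integer-coded sequences;
# fitness is evaluated per step for all trials at once and move proposals run
# through the compiled engine
run_trial_batch <- function(parent_codes, eval_fit, cfg) {
  nt <- cfg$n_trials
  current <- parent_codes[sample.int(length(parent_codes), nt, replace = TRUE)]
  f_cur <- eval_fit(current)
  best <- current; f_best <- f_cur
  for (s in seq_len(cfg$n_steps)) {
    cand <- cpp_ga_batch_propose(current, parent_codes, cfg$p_crossover,
                                 cfg$p_mutation, cfg$p_deletion, cfg$p_growth,
                                 cfg$len_min, cfg$len_max)
    f_cand <- eval_fit(cand)
    tie <- f_cand == f_cur & runif(nt) < 0.5
    acc <- f_cand > f_cur | tie
    current[acc] <- cand[acc]
    f_cur[acc] <- f_cand[acc]
    improved <- f_cur >= f_best   # ties keep the most recent state
    best[improved] <- current[improved]
    f_best[improved] <- f_cur[improved]
  }
  list(codes = best, fitness = f_best)
}
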