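# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities with the most naive algorithm available so they stay
# independent of the package's implementation paths.

PARAMS <- load_parameter_table()
SCALER <- default_scaler_config(PARAMS)

# literal double-loop SCD: (1/N) sum_{m>n} q_m q_n sqrt(m - n)
brute_scd <- function(seq) {
  q <- PARAMS$residues[strsplit(seq, "")[[1]], "charge"]
  N <- length(q)
  s <- 0
  for (m in 2:N) for (n in 1:(m - 1)) s <- s + q[m] * q[n] * sqrt(m - n)
  s / N
}

# literal double-loop SHD: (1/N) sum_{m>n} (lam_m + lam_n) / (m - n)
brute_shd <- function(seq) {
  l <- PARAMS$residues[strsplit(seq, "")[[1]], "lambda"]
  N <- length(l)
  s <- 0
  for (m in 2:N) for (n in 1:(m - 1)) s <- s + (l[m] + l[n]) / (m - n)
  s / N
}

# O(n^2) dominance scan, both objectives maximized
brute_pareto <- function(pts) {
  n <- nrow(pts)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      dom <- pts[j, 1] >= pts[i, 1] && pts[j, 2] >= pts[i, 2] &&
        (pts[j, 1] > pts[i, 1] || pts[j, 2] > pts[i, 2])
      if (dom) { keep[i] <- FALSE; break }
      if (j < i && pts[j, 1] == pts[i, 1] && pts[j, 2] == pts[i, 2]) {
        keep[i] <- FALSE; break   # duplicate: first-seen wins
      }
    }
  }
  which(keep)
}

# fine-grid area estimate of the dominated hypervolume
grid_hypervolume <- function(front, ref, n_grid = 600) {
  xs <- seq(ref[1], max(front[, 1]), length.out = n_grid)
  ys <- seq(ref[2], max(front[, 2]), length.out = n_grid)
  dx <- diff(xs)[1]; dy <- diff(ys)[1]
  cx <- xs[-1] - dx / 2; cy <- ys[-1] - dy / 2
  covered <- matrix(FALSE, length(cx), length(cy))
  for (k in seq_len(nrow(front))) {
    covered <- covered | outer(cx <= front[k, 1], cy <= front[k, 2], "&")
  }
  sum(covered) * dx * dy
}

# Monte-Carlo EHVI with independent Gaussian draws; returns estimate and SE
mc_ehvi <- function(mu1, sd1, mu2, sd2, front, ref, n_draw = 1e5) {
  y1 <- rnorm(n_draw, mu1, sd1)
  y2 <- rnorm(n_draw, mu2, sd2)
  o <- order(front[, 1])
  a <- front[o, 1]; b <- front[o, 2]
  n <- length(a)
  hvi <- numeric(n_draw)
  for (i in seq_len(n + 1)) {
    lo <- if (i == 1) ref[1] else a[i - 1]
    hi <- if (i == n + 1) Inf else a[i]
    H <- if (i == n + 1) ref[2] else b[i]
    w <- pmax(pmin(y1, hi) - lo, 0)
    h <- pmax(y2 - H, 0)
    hvi <- hvi + w * h
  }
  list(mean = mean(hvi), se = sd(hvi) / sqrt(n_draw))
}

# 3-d Brownian chain trajectories with known diffusion coefficient
gen_brownian <- function(n_chain = 100, n_frame = 200, dt = 1, D = 1,
                         seed = 1) {
  set.seed(seed)
  pos <- array(0, dim = c(n_frame, n_chain, 3))
  sd_step <- sqrt(2 * D * dt)
  for (t in 2:n_frame) {
    pos[t, , ] <- pos[t - 1, , ] + rnorm(n_chain * 3, sd = sd_step)
  }
  pos
}

random_sequences <- function(n, len_range = c(20, 50), seed = 1) {
  set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(len_range[1]:len_range[2], 1)
    paste(sample(AA_ALPHABET_TEST, L, replace = TRUE), collapse = "")
  }, "")
}
AA_ALPHABET_TEST <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                      "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
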