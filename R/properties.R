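# Desk-scale physical property engines: B2 from a potential of mean force,
# equation-of-state phase analysis, self-diffusion from mean-squared
# displacement, reference scales, and the homopolymer scaling analysis.

#' Construct a potential-of-mean-force curve
#'
#' @param r_grid strictly increasing center-of-mass distances (Angstrom).
#' @param u potential of mean force at each distance (kcal/mol); may contain
#'   \code{Inf} for hard-core overlap.
#' @param temperature K.
#' @param u_se optional per-bin standard errors.
#' @return object of class \code{pmf_curve}.
#' @export
pmf_curve <- function(r_grid, u, temperature = 300, u_se = NULL) {
  stopifnot(length(r_grid) == length(u), all(diff(r_grid) > 0),
            all(r_grid > 0))
  structure(list(r = r_grid, u = u, temperature = temperature, u_se = u_se),
            class = "pmf_curve")
}

#' Second virial coefficient from a PMF curve
#'
#' \eqn{B_2 = 2\pi \int_0^{r_{max}} r^2 [1 - e^{-\beta u(r)}] dr} by composite
#' trapezoid quadrature on the curve's grid; beyond the last point u is taken
#' as 0. Non-finite u values are treated as hard-core overlap (integrand
#' \eqn{r^2}); a contiguous hard-core prefix is integrated exactly up to the
#' midpoint between the last overlapping and first finite grid point, so a
#' discontinuity placed between grid points is located to second order.
#'
#' @param pmf a \code{pmf_curve}.
#' @return list with \code{B2} (Angstrom^3) and \code{B2_se} (propagated from
#'   per-bin PMF uncertainties when present, else \code{NA}).
#' @export
b2_from_pmf <- function(pmf) {
  stopifnot(inherits(pmf, "pmf_curve"))
  beta <- 1 / (KB_KCAL * pmf$temperature)
  r <- pmf$r
  g <- exp(-beta * pmf$u)
  g[!is.finite(pmf$u)] <- 0
  integrand <- r^2 * (1 - g)
  fin <- is.finite(pmf$u)
  if (!fin[1]) {
    fs <- which(fin)[1]
    if (is.na(fs)) stop("PMF is non-finite everywhere")
    r_hc <- (r[fs - 1] + r[fs]) / 2
    B2 <- 2 * pi * (r_hc^3 / 3 +
                      trapz(c(r_hc, r[fs:length(r)]),
                            c(integrand[fs], integrand[fs:length(r)])))
  } else {
    # below the first grid point, continue the first integrand value
    core <- integrand[1] / r[1]^2 * r[1]^3 / 3
    B2 <- 2 * pi * (core + trapz(r, integrand))
  }
  se <- NA_real_
  if (!is.null(pmf$u_se)) {
    # dB2/du_i = 2*pi * w_i * r_i^2 * beta * exp(-beta u_i) with trapezoid
    # weights w_i
    n <- length(r)
    w <- numeric(n)
    dr <- diff(r)
    w[1] <- dr[1] / 2; w[n] <- dr[n - 1] / 2
    if (n > 2) w[2:(n - 1)] <- (dr[-1] + dr[-(n - 1)]) / 2
    dB <- 2 * pi * w * r^2 * beta * g
    dB[!is.finite(dB)] <- 0
    se <- sqrt(sum((dB * pmf$u_se)^2, na.rm = TRUE))
  }
  list(B2 = B2, B2_se = se)
}

#' Exact PMF of two single beads
#'
#' For two single residues the center-of-mass PMF equals the nonbonded pair
#' potential; used as the exact oracle for the Monte-Carlo sampler.
#'
#' @param res_i,res_j one-letter residue codes.
#' @param params an \code{idp_params}.
#' @param r_grid distances (Angstrom).
#' @return a \code{pmf_curve}.
#' @export
pair_pmf_exact <- function(res_i, res_j, params = load_parameter_table(),
                           r_grid = seq(0.2, 100, by = 0.2)) {
  u <- total_pair_potential(r_grid, res_i, res_j, params)
  pmf_curve(r_grid, u, temperature = params$temperature)
}

# Metropolis sampling of an isolated chain's conformations under the bonded +
# intramolecular nonbonded CG energy. Returns a list of n_conf coordinate
# matrices (N x 3) with centered center of mass.
sample_chain_conformations <- function(codes, params, n_conf = 100,
                                       n_equil = 200, thin = 10) {
  N <- length(codes)
  res <- AA_ALPHABET[codes]
  b0 <- params$bond_b0
  if (N == 1) {
    return(replicate(n_conf, matrix(0, 1, 3), simplify = FALSE))
  }
  energy <- function(x) {
    bl <- sqrt(rowSums((x[-1, , drop = FALSE] - x[-N, , drop = FALSE])^2))
    e <- sum(params$bond_k * (bl - b0)^2)
    if (N > 2) {
      for (i in 1:(N - 2)) {
        for (j in (i + 2):N) {
          r <- sqrt(sum((x[i, ] - x[j, ])^2))
          e <- e + total_pair_potential(r, res[i], res[j], params)
        }
      }
    }
    e
  }
  beta <- 1 / (KB_KCAL * params$temperature)
  x <- cbind(seq(0, by = b0, length.out = N), 0, 0)
  e <- energy(x)
  out <- vector("list", n_conf)
  step <- 0.6
  total <- n_equil + n_conf * thin
  k <- 0
  for (it in seq_len(total)) {
    i <- sample.int(N, 1)
    prop <- x
    prop[i, ] <- prop[i, ] + rnorm(3, sd = step)
    ep <- energy(prop)
    if (log(runif(1)) < -beta * (ep - e)) {
      x <- prop; e <- ep
    }
    if (it > n_equil && (it - n_equil) %% thin == 0) {
      k <- k + 1
      out[[k]] <- sweep(x, 2, colMeans(x))
    }
  }
  out
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Monte-Carlo potential of mean force between two short chains
#'
#' Desk-scale estimator of the center-of-mass PMF between two flexible chains
#' interacting through the CG pair energies. Conformations of each chain are
#' sampled from the isolated-chain Boltzmann ensemble by Metropolis Monte
#' Carlo; at each COM distance r the PMF follows exactly from
#' \eqn{u(r) = -k_BT \ln \langle e^{-\beta U_{inter}} \rangle} where the
#' average runs over independent conformation pairs and random mutual
#' orientations at fixed COM separation. Per-bin standard errors are obtained
#' by the delta method.
#'
#' @param seq_a,seq_b sequences (length <= \code{max_len}).
#' @param params an \code{idp_params}.
#' @param r_grid COM distances (Angstrom).
#' @param n_samples orientation/conformation samples per bin.
#' @param n_conf stored conformations per chain.
#' @param max_len maximum chain length accepted (desk-scale guard).
#' @param seed RNG seed.
#' @return a \code{pmf_curve} with per-bin standard errors.
#' @export
two_chain_pmf_mc <- function(seq_a, seq_b, params = load_parameter_table(),
                             r_grid = seq(2, 60, by = 1), n_samples = 200,
                             n_conf = 80, max_len = 10, seed = 1) {
  ca <- seq_to_codes(seq_a); cb <- seq_to_codes(seq_b)
  if (length(ca) > max_len || length(cb) > max_len) {
    stop("chain length exceeds the configured desk-scale maximum (", max_len, ")")
  }
  set.seed(seed)
  beta <- 1 / (KB_KCAL * params$temperature)
  confs_a <- sample_chain_conformations(ca, params, n_conf = n_conf)
  confs_b <- sample_chain_conformations(cb, params, n_conf = n_conf)
  lamA <- params$residues$lambda[ca]
  resA <- AA_ALPHABET[ca]; resB <- AA_ALPHABET[cb]
  u <- u_se <- numeric(length(r_grid))
  flagged <- logical(length(r_grid))
  for (bi in seq_along(r_grid)) {
    r <- r_grid[bi]
    w <- numeric(n_samples)
    for (s in seq_len(n_samples)) {
      xa <- confs_a[[sample.int(n_conf, 1)]] %*% random_rotation()
      xb <- confs_b[[sample.int(n_conf, 1)]] %*% random_rotation()
      xb[, 1] <- xb[, 1] + r
      e <- 0
      for (i in seq_along(ca)) {
        d <- sqrt((xb[, 1] - xa[i, 1])^2 + (xb[, 2] - xa[i, 2])^2 +
                    (xb[, 3] - xa[i, 3])^2)
        e <- e + sum(total_pair_potential(d, resA[i], resB, params))
      }
      w[s] <- -beta * e
    }
    # stable log-mean-exp so deep overlap energies do not underflow
    m <- max(w)
    if (!is.finite(m)) {
      u[bi] <- Inf; u_se[bi] <- Inf; flagged[bi] <- TRUE
    } else {
      ws <- exp(w - m)
      mw <- mean(ws)
      u[bi] <- -(m + log(mw)) / beta
      u_se[bi] <- sd(ws) / (mw * sqrt(n_samples)) / beta
      flagged[bi] <- mean(ws > 1e-12) < 0.05
    }
  }
  out <- pmf_curve(r_grid, u, temperature = params$temperature, u_se = u_se)
  out$flagged <- flagged
  out
}

#' Construct an equation-of-state curve
#'
#' @param densities g/ml, strictly increasing after sorting.
#' @param pressures pressure values (any consistent unit).
#' @param pressure_se per-point standard errors (default 0).
#' @param temperature K.
#' @return object of class \code{eos_curve}, sorted by density.
#' @export
eos_curve <- function(densities, pressures, pressure_se = NULL,
                      temperature = 300) {
  stopifnot(length(densities) == length(pressures))
  if (is.null(pressure_se)) pressure_se <- rep(0, length(densities))
  o <- order(densities)
  if (anyDuplicated(densities)) stop("duplicated density points")
  structure(list(rho = densities[o], p = pressures[o],
                 p_se = pressure_se[o], temperature = temperature),
            class = "eos_curve")
}

.eos_rho_c <- function(rho, p, n_grid = 2000) {
  f <- splinefun(rho, p, method = "natural")
  g <- seq(min(rho), max(rho), length.out = n_grid)
  pg <- f(g)
  sep <- any(pg[-c(1, n_grid)] < 0)
  if (!sep) return(list(phase = FALSE, rho_c = NA_real_))
  if (pg[n_grid] < 0) {
    return(list(phase = TRUE, rho_c = NA_real_, unresolved = TRUE))
  }
  # highest density at which the fitted pressure crosses zero
  cross <- which(pg[-n_grid] < 0 & pg[-1] >= 0)
  i <- max(cross)
  root <- uniroot(f, lower = g[i], upper = g[i + 1])$root
  list(phase = TRUE, rho_c = root, unresolved = FALSE)
}

#' Equation-of-state phase-separation analysis
#'
#' Fits a cubic spline to the pressure-density equation of state, flags phase
#' separation when the fitted pressure dips below zero at an interior density
#' (the finite-size van der Waals loop criterion with a near-zero coexistence
#' pressure), and extracts the condensed-phase density \eqn{\rho_c} as the
#' highest density at which the fitted pressure crosses zero. Uncertainty via
#' 50 Gaussian bootstrap resamples of the per-point pressures.
#'
#' @param eos an \code{eos_curve} (at least 4 density points).
#' @param n_boot bootstrap resamples (default 50).
#' @param seed RNG seed for the bootstrap.
#' @return list with \code{phase_separates}, \code{rho_c}, \code{rho_c_se},
#'   and \code{unresolved} (TRUE when the condensed branch never returns to
#'   positive pressure inside the sampled density window).
#' @export
eos_phase_analysis <- function(eos, n_boot = 50, seed = 1) {
  stopifnot(inherits(eos, "eos_curve"))
  if (length(eos$rho) < 4) stop("need at least 4 density points")
  base <- .eos_rho_c(eos$rho, eos$p)
  if (!base$phase) {
    return(list(phase_separates = FALSE, rho_c = NA_real_,
                rho_c_se = NA_real_, unresolved = FALSE))
  }
  if (isTRUE(base$unresolved)) {
    warning("pressure negative at the highest sampled density; ",
            "condensed branch unresolved")
    return(list(phase_separates = TRUE, rho_c = NA_real_,
                rho_c_se = NA_real_, unresolved = TRUE))
  }
  set.seed(seed)
  boots <- replicate(n_boot, {
    pb <- eos$p + rnorm(length(eos$p), sd = eos$p_se)
    bb <- .eos_rho_c(eos$rho, pb)
    if (bb$phase && !isTRUE(bb$unresolved)) bb$rho_c else NA_real_
  })
  list(phase_separates = TRUE, rho_c = base$rho_c,
       rho_c_se = stats::sd(boots, na.rm = TRUE), unresolved = FALSE)
}

#' Self-diffusion coefficient from mean-squared displacement
#'
#' Computes the chain center-of-mass MSD averaged over chains and time
#' origins and estimates \eqn{D} as slope/6 of a linear fit over the
#' configured long-time window. The default window uses lags between 40% and
#' 100% of one tenth of the trajectory length: long enough to sit in the
#' diffusive regime, short enough that each chain still contributes many
#' independent displacement segments (the statistical error of the MSD grows
#' with the lag as time-origin averages decorrelate). A log-log diagnostic
#' slope far from 1 triggers a warning (sub-linear plateau or ballistic
#' motion).
#'
#' @param times frame times (uniform spacing).
#' @param positions array \code{[frame, chain, 3]} of chain COM coordinates.
#' @param fit_window fraction of the lag range used for the fit, as
#'   \code{c(lo, hi)} in (0, 1]; default \code{c(0.4, 1)}.
#' @param max_lag_frac largest lag as a fraction of the trajectory (default
#'   0.1).
#' @return list with \code{D}, \code{D_se} (slope standard error / 6),
#'   \code{msd} data.frame, and \code{loglog_slope} diagnostic.
#' @export
diffusion_from_msd <- function(times, positions, fit_window = c(0.4, 1),
                               max_lag_frac = 0.1) {
  nt <- length(times)
  stopifnot(nt >= 2, dim(positions)[1] == nt, dim(positions)[3] == 3)
  dt <- diff(times)
  if (max(abs(dt - dt[1])) > 1e-8 * abs(dt[1])) {
    stop("non-uniform time spacing")
  }
  nlag <- max(2, floor(nt * max_lag_frac))
  lags <- seq_len(nlag)
  msd <- vapply(lags, function(l) {
    d <- positions[(l + 1):nt, , , drop = FALSE] -
      positions[1:(nt - l), , , drop = FALSE]
    3 * mean(d * d)   # mean over frames/chains of the 3-component sum
  }, numeric(1))
  tau <- lags * dt[1]
  lo <- max(1, ceiling(fit_window[1] * nlag))
  hi <- min(nlag, floor(fit_window[2] * nlag))
  if (hi - lo < 2) stop("trajectory too short for the requested fit window")
  fit <- lm(msd[lo:hi] ~ tau[lo:hi])
  slope <- unname(coef(fit)[2])
  se <- unname(summary(fit)$coefficients[2, 2])
  ll <- NA_real_
  if (all(msd[lo:hi] > 0)) {
    ll <- unname(coef(lm(log(msd[lo:hi]) ~ log(tau[lo:hi])))[2])
    if (ll < 0.7 || ll > 1.3) {
      warning(sprintf(paste0("MSD is not linear in the fit window ",
                             "(log-log slope %.2f); D estimate unreliable"),
                      ll))
    }
  }
  list(D = max(slope, 0) / 6, D_se = se / 6,
       msd = data.frame(lag = tau, msd = msd), loglog_slope = ll)
}

#' Reference volume and diffusion scales
#'
#' \eqn{V_0 = (4\pi/3) b_0^3 (N/6)^{3/2}} is the pervaded volume of an ideal
#' chain (b0 = 3.8 Angstrom) and \eqn{D_0 = \tau k_B T / (N \bar M)} the
#' self-diffusion scale of an ideal Rouse chain with damping time
#' \eqn{\tau = 1} ps and \eqn{\bar M} the mean residue mass of the parameter
#' table. For N = 50 at 300 K these evaluate to 5529 Angstrom^3 and
#' 0.42e-9 m^2/s.
#'
#' @param N chain length.
#' @param temperature K.
#' @param params an \code{idp_params}.
#' @param tau_ps Langevin damping time in ps.
#' @return list with \code{V0} (Angstrom^3), \code{D0} (m^2/s), \code{tau},
#'   \code{Mbar}, \code{b0_ref}.
#' @export
reference_scales <- function(N = 50, temperature = 300,
                             params = load_parameter_table(), tau_ps = 1) {
  stopifnot(N >= 1)
  V0 <- (4 * pi / 3) * params$b0_ref^3 * (N / 6)^1.5
  Mbar <- mean(params$residues$mass)
  kB <- 1.380649e-23
  mass_kg <- N * Mbar * 1e-3 / 6.02214076e23
  D0 <- tau_ps * 1e-12 * kB * temperature / mass_kg
  list(V0 = V0, D0 = D0, tau = tau_ps, Mbar = Mbar, b0_ref = params$b0_ref)
}

#' Homopolymer thermodynamics-dynamics scaling analysis
#'
#' Tests the Rouse-argument scaling \eqn{D \sim -N^{1/2} B_2} on a set of
#' phase-separating records: fits \eqn{\log(D/D_0)} against
#' \eqn{\log(-B_2 N^{1/2}/V_0)} and reports the correlation alongside the
#' unscaled regressor \eqn{\log(-B_2/V_0)}.
#'
#' @param records data.frame with columns \code{N}, \code{B2}, \code{D}.
#' @param temperature K.
#' @param params an \code{idp_params}.
#' @return list with \code{slope}, \code{intercept}, \code{correlation},
#'   \code{correlation_unscaled}, \code{n_used}.
#' @export
homopolymer_scaling <- function(records, temperature = 300,
                                params = load_parameter_table()) {
  keep <- records$B2 < 0 & records$D > 0
  if (any(!keep)) {
    warning(sum(!keep), " record(s) with nonnegative B2 or D excluded")
  }
  records <- records[keep, , drop = FALSE]
  if (nrow(records) < 3) stop("need at least 3 phase-separating records")
  ref <- reference_scales(50, temperature, params)
  y <- log(records$D / ref$D0)
  x <- log(-records$B2 * sqrt(records$N) / ref$V0)
  x0 <- log(-records$B2 / ref$V0)
  fit <- lm(y ~ x)
  r_unscaled <- if (sd(x0) > 0) cor(y, x0) else NA_real_
  r_scaled <- if (sd(x) > 0) cor(y, x) else NA_real_
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       correlation = r_scaled, correlation_unscaled = r_unscaled,
       n_used = nrow(records))
}
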