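test_that("B2 quadrature reproduces closed forms and the ideal-gas limit", {
  r <- seq(0.1, 100, by = 0.2)
  expect_equal(b2_from_pmf(pmf_curve(r, rep(0, length(r))))$B2, 0)
  sig <- 10
  hs <- b2_from_pmf(pmf_curve(r, ifelse(r < sig, Inf, 0)))$B2
  expect_equal(hs, 2 * pi * sig^3 / 3, tolerance = 1e-3)
  lam <- 1.5; epsw <- 0.3
  beta <- 1 / (0.0019872041 * 300)
  sw <- b2_from_pmf(pmf_curve(r, ifelse(r < sig, Inf,
                                        ifelse(r < lam * sig, -epsw, 0))))$B2
  exact <- (2 * pi / 3) * (sig^3 - (lam^3 - 1) * sig^3 * (exp(beta * epsw) - 1))
  expect_equal(sw, exact, tolerance = 1e-3)
})

test_that("B2 is monotone in the well depth", {
  r <- seq(0.2, 60, by = 0.2)
  p <- PARAMS
  u <- total_pair_potential(r, "F", "F", p)
  set.seed(5)
  for (i in 1:5) {
    deepen <- runif(length(r), 0, 0.2) * (u < 0)
    expect_lte(b2_from_pmf(pmf_curve(r, u - deepen))$B2,
               b2_from_pmf(pmf_curve(r, u))$B2)
  }
})

test_that("exact single-bead PMF matches the pair potential and decays", {
  grid <- seq(0.4, 100, by = 0.4)
  pmf <- pair_pmf_exact("G", "G", PARAMS, grid)
  expect_equal(pmf$u, total_pair_potential(grid, "G", "G", PARAMS))
  # attractive screened-Coulomb tail for an E-K pair
  tail_u <- pair_pmf_exact("E", "K", PARAMS, grid)$u[grid > 12 & grid < 40]
  expect_true(all(tail_u < 0))
  for (pr in list(c("W", "W"), c("E", "K"), c("R", "R"))) {
    expect_lt(abs(pair_pmf_exact(pr[1], pr[2], PARAMS, grid)$u[length(grid)]),
              2e-6)   # screened-Coulomb tail at 100 A is ~1e-6 kcal/mol
  }
})

test_that("Monte-Carlo PMF of two single beads equals the exact pair potential", {
  grid <- seq(2, 50, by = 1)
  for (seed in 1:3) {
    mc <- two_chain_pmf_mc("W", "G", PARAMS, r_grid = grid, n_samples = 40,
                           n_conf = 10, seed = seed)
    ex <- pair_pmf_exact("W", "G", PARAMS, grid)
    expect_equal(mc$u, ex$u, tolerance = 1e-9)
    expect_true(all(mc$u_se[is.finite(mc$u_se)] < 1e-9))
  }
  # fixed seed gives a bit-identical curve
  a <- two_chain_pmf_mc("EK", "GW", PARAMS, r_grid = grid, n_samples = 30,
                        n_conf = 15, seed = 11)
  b <- two_chain_pmf_mc("EK", "GW", PARAMS, r_grid = grid, n_samples = 30,
                        n_conf = 15, seed = 11)
  expect_identical(a$u, b$u)
  expect_error(two_chain_pmf_mc(strrep("A", 11), "G", PARAMS), "desk-scale")
})

test_that("athermal neutral beads give a nonnegative PMF", {
  p <- PARAMS
  p$residues["G", "lambda"] <- 0
  mc <- two_chain_pmf_mc("G", "G", p, r_grid = seq(2, 30, by = 1),
                         n_samples = 30, n_conf = 10, seed = 2)
  expect_true(all(mc$u >= -1e-12))
})

test_that("EOS analysis recovers the planted highest zero-crossing", {
  rho <- seq(0.2, 1.2, by = 0.1)
  pfun <- function(x) 40 * (x - 0.3) * (x - 0.8) * (x + 0.4)
  res <- eos_phase_analysis(eos_curve(rho, pfun(rho)), seed = 3)
  expect_true(res$phase_separates)
  expect_equal(res$rho_c, 0.8, tolerance = 0.01)
  expect_equal(res$rho_c_se, 0)   # zero-variance bootstrap is degenerate

  # reordering the input points does not change the analysis
  o <- sample(length(rho))
  res2 <- eos_phase_analysis(eos_curve(rho[o], pfun(rho)[o]), seed = 3)
  expect_equal(res2$rho_c, res$rho_c)

  # bootstrap SE is positive once the pressures carry uncertainty
  res3 <- eos_phase_analysis(eos_curve(rho, pfun(rho),
                                       pressure_se = rep(0.5, length(rho))),
                             seed = 3)
  expect_gt(res3$rho_c_se, 0)
  expect_equal(res3$rho_c, res$rho_c)

  # strictly positive increasing EOS: no phase separation
  none <- eos_phase_analysis(eos_curve(rho, 5 + 10 * rho), seed = 1)
  expect_false(none$phase_separates)
  expect_true(is.na(none$rho_c))

  # pressure still negative at the top density: unresolved condensed branch
  expect_warning(
    un <- eos_phase_analysis(eos_curve(rho, 1 - 4 * rho), seed = 1),
    "unresolved")
  expect_true(un$unresolved)
  expect_error(eos_phase_analysis(eos_curve(rho[1:3], pfun(rho)[1:3])),
               "at least 4")
})

test_that("rho_c matches a dense-grid sign scan on random vdW loops", {
  set.seed(8)
  rho <- seq(0.2, 1.2, by = 0.05)
  for (i in 1:5) {
    r1 <- runif(1, 0.3, 0.5); r2 <- runif(1, 0.6, 1.0)
    p <- runif(1, 10, 60) * (rho - r1) * (rho - r2) * (rho + runif(1, 0.1, 1))
    res <- eos_phase_analysis(eos_curve(rho, p), seed = i)
    # brute-force oracle: densest sign change of the fitted spline
    f <- splinefun(rho, p, method = "natural")
    g <- seq(0.2, 1.2, length.out = 20001)
    sg <- f(g)
    cross <- which(sg[-length(sg)] < 0 & sg[-1] >= 0)
    brute <- g[max(cross)]
    expect_equal(res$rho_c, brute, tolerance = 1e-3)
    expect_equal(res$rho_c, r2, tolerance = 0.01)
  }
})

test_that("MSD estimator recovers planted diffusion and flags pathologies", {
  pos <- gen_brownian(n_chain = 60, n_frame = 150, dt = 1, D = 1, seed = 4)
  est <- diffusion_from_msd(seq_len(150), pos)
  expect_equal(est$D, 1, tolerance = 0.05)
  expect_gt(est$D_se, 0)

  still <- array(2, dim = c(50, 5, 3))
  est0 <- diffusion_from_msd(seq_len(50), still)
  expect_equal(est0$D, 0)

  t <- seq_len(80)
  ball <- array(0, dim = c(80, 3, 3))
  for (ch in 1:3) for (d in 1:3) ball[, ch, d] <- 0.5 * t
  expect_warning(diffusion_from_msd(t, ball), "not linear")
  expect_error(diffusion_from_msd(c(1, 2, 4), array(0, c(3, 2, 3))),
               "non-uniform")
})

test_that("reference scales reproduce the N = 50 closed-form values", {
  rs <- reference_scales(50, 300, PARAMS)
  expect_equal(round(rs$V0), 5529)
  expect_equal(round(rs$D0 * 1e9, 2), 0.42)
  expect_equal(rs$Mbar, mean(PARAMS$residues$mass))
  # V0 scales as N^(3/2)
  expect_equal(reference_scales(40, 300, PARAMS)$V0 /
                 reference_scales(10, 300, PARAMS)$V0, 8)
  # D0 scales as 1/N
  expect_equal(reference_scales(25, 300, PARAMS)$D0 /
                 reference_scales(50, 300, PARAMS)$D0, 2)
})

test_that("homopolymer scaling analysis detects the N^(1/2) law", {
  rs <- reference_scales(50, 300, PARAMS)
  set.seed(6)
  N <- sample(c(20, 30, 40, 50), 24, replace = TRUE)
  B2 <- -rs$V0 * runif(24, 2, 60)
  D <- 3 * rs$D0 * rs$V0 / (-B2 * sqrt(N))   # exactly on the law
  fit <- homopolymer_scaling(data.frame(N = N, B2 = B2, D = D), 300, PARAMS)
  expect_equal(abs(fit$correlation), 1, tolerance = 1e-12)
  expect_equal(fit$slope, -1, tolerance = 1e-10)
  expect_lt(abs(fit$correlation_unscaled), 1)

  # scrambling the N^(1/2) factor weakens the scaled correlation
  D_scr <- 3 * rs$D0 * rs$V0 / (-B2 * sqrt(sample(N)))
  fit_scr <- homopolymer_scaling(data.frame(N = N, B2 = B2, D = D_scr),
                                 300, PARAMS)
  expect_lt(abs(fit_scr$correlation), 1 - 1e-6)

  # at a single chain length the N factor cannot matter
  one <- N == 40
  if (sum(one) >= 3) {
    f1 <- homopolymer_scaling(data.frame(N = N[one], B2 = B2[one], D = D[one]),
                              300, PARAMS)
    expect_equal(abs(f1$correlation), abs(f1$correlation_unscaled),
                 tolerance = 1e-12)
  }

  # nonnegative-B2 records are excluded with a warning
  expect_warning(
    homopolymer_scaling(data.frame(N = c(N, 30), B2 = c(B2, 100),
                                   D = c(D, rs$D0)), 300, PARAMS),
    "excluded")
})
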