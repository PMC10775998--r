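test_that("pareto_front matches brute-force dominance on random clouds", {
  expect_equal(pareto_front(matrix(c(3, 4), ncol = 2)), 1L)
  # a chain of mutually nondominated points is fully retained
  chain <- cbind(1:6, 6:1)
  expect_equal(sort(pareto_front(chain)), 1:6)
  set.seed(20)
  for (i in 1:4) {
    pts <- cbind(rnorm(200), rnorm(200))
    expect_setequal(pareto_front(pts), brute_pareto(pts))
  }
  # exact ties on both coordinates keep the first-seen point
  tied <- rbind(c(1, 1), c(1, 1), c(0.5, 0.2))
  expect_equal(pareto_front(tied), 1L)
})

test_that("hypervolume agrees with hand values and a grid oracle", {
  expect_equal(hypervolume(matrix(c(1, 1), ncol = 2), c(0, 0)), 1)
  expect_equal(hypervolume(rbind(c(1, 2), c(2, 1)), c(0, 0)), 3)
  set.seed(21)
  for (i in 1:3) {
    pts <- cbind(runif(12, 1, 4), runif(12, 1, 4))
    hv <- hypervolume(pts, c(0.5, 0.5))
    front <- pts[pareto_front(pts), , drop = FALSE]
    expect_equal(hv, grid_hypervolume(front, c(0.5, 0.5)), tolerance = 0.01)
  }
  # monotonicity: adding a nondominated point strictly increases the area
  pts <- rbind(c(1, 3), c(3, 1))
  expect_gt(hypervolume(rbind(pts, c(2.5, 2.5)), c(0, 0)),
            hypervolume(pts, c(0, 0)))
  expect_warning(hypervolume(rbind(c(1, 1), c(-1, 5)), c(0, 0)), "reference")
})

test_that("psi closed form matches numerical integration", {
  cases <- list(c(1, 0, 0, 1), c(2, 1.5, -0.5, 0.7), c(-1, 0.2, 0.4, 2),
                c(0, 3, 1, 0.3))
  for (cs in cases) {
    num <- integrate(function(z) (cs[1] - z) * dnorm(z, cs[3], cs[4]),
                     -Inf, cs[2], rel.tol = 1e-12)$value
    expect_equal(psi(cs[1], cs[2], cs[3], cs[4]), num, tolerance = 1e-8)
  }
  expect_equal(psi(1, -50, 0, 1), 0, tolerance = 1e-12)
  # sigma -> 0 limit behaves as a step in mu
  expect_equal(psi(2, 1, 0.5, 0), 1.5)
  expect_equal(psi(2, 1, 1.5, 0), 0)
})

test_that("EHVI limits: dominated candidates score zero, deterministic candidates score the hypervolume gain", {
  front <- rbind(c(1, 3), c(2, 2), c(3, 1))
  ref <- c(0, 0)
  tiny <- 1e-12
  dominated <- ehvi(list(mean = -0.5, sd = tiny), list(mean = 0.5, sd = tiny),
                    front, ref)
  expect_equal(dominated, 0, tolerance = 1e-9)
  mu <- c(4, 4)
  gain <- hypervolume(rbind(front, mu), ref) - hypervolume(front, ref)
  det <- ehvi(list(mean = mu[1], sd = tiny), list(mean = mu[2], sd = tiny),
              front, ref)
  expect_equal(det, gain, tolerance = 1e-6)
  # interior deterministic candidate: rectangle sliver it adds
  mu2 <- c(2.5, 2.5)
  gain2 <- hypervolume(rbind(front, mu2), ref) - hypervolume(front, ref)
  expect_equal(ehvi(list(mean = 2.5, sd = tiny), list(mean = 2.5, sd = tiny),
                    front, ref), gain2, tolerance = 1e-6)
})

test_that("exact EHVI matches Monte-Carlo estimates on random instances", {
  set.seed(22)
  for (i in 1:8) {
    npts <- sample(1:5, 1)
    raw <- cbind(runif(npts, 0, 3), runif(npts, 0, 3))
    front <- raw[pareto_front(raw), , drop = FALSE]
    ref <- c(-0.5, -0.5)
    mu1 <- runif(1, -1, 4); mu2 <- runif(1, -1, 4)
    sd1 <- runif(1, 0.1, 1); sd2 <- runif(1, 0.1, 1)
    mc <- mc_ehvi(mu1, sd1, mu2, sd2, front, ref, n_draw = 4e4)
    ex <- ehvi(list(mean = mu1, sd = sd1), list(mean = mu2, sd = sd2),
               front, ref)
    expect_gte(ex, 0)
    expect_lt(abs(ex - mc$mean), 3 * mc$se + 1e-4)
  }
})

test_that("similarity penalty follows the harmonic-mean reading", {
  x <- c(1, 0)
  expect_equal(similarity_penalty(x, NULL), 1)
  expect_equal(similarity_penalty(x, matrix(x, nrow = 1)), 0)
  # history with cosines 0 and 0.5 -> dissimilarities 0.5, 0.25 -> alpha 1/3
  h <- rbind(c(0, 1), c(0.5, sqrt(3) / 2))
  expect_equal(similarity_penalty(x, h), 1 / 3, tolerance = 1e-12)
  # permutation invariance and bounds on random feature sets
  set.seed(23)
  H <- matrix(runif(60), ncol = 6)
  cand <- runif(6)
  a1 <- similarity_penalty(cand, H)
  a2 <- similarity_penalty(cand, H[sample(10), ])
  expect_equal(a1, a2)
  expect_gte(a1, 0); expect_lte(a1, 1)
  expect_error(similarity_penalty(rep(0, 6), H), "zero-norm")
})

test_that("stage fitness functions rank candidates as specified", {
  set.seed(24)
  n <- 40
  X <- matrix(runif(n * 3), ncol = 3)
  B2 <- -10 * X[, 1] + rnorm(n, sd = 0.01)
  D <- 5 * X[, 2] + rnorm(n, sd = 0.01)
  b2m <- fit_b2_gpr(X, B2, maxit = 40)
  dm <- fit_d_gpr(X, D, maxit = 40)

  f0 <- make_fitness(0, b2_model = b2m)
  expect_equal(order(f0(X)), order(-predict(b2m, X)$mean))

  f8 <- make_fitness(8, k_final = 8, b2_model = b2m, d_model = dm)
  expect_equal(f8(X), -predict(b2m, X)$mean + predict(dm, X)$mean,
               tolerance = 1e-10)
  # two candidates with combined standardized scores 1.2 vs 0.7
  hi <- which.max(-predict(b2m, X)$mean + predict(dm, X)$mean)
  expect_equal(which.max(f8(X)), hi)

  # classifier gate: label 0 forces zero fitness regardless of EHVI
  lab <- X[, 3] > 0.5
  cl <- fit_phase_classifier(X, lab, ntree = 101, seed = 1)
  front <- rbind(c(0.5, 0.5), c(1, 0.2))
  fe <- make_fitness(3, k_final = 8, b2_model = b2m, d_model = dm,
                     classifier = cl, front = front, reference = c(-2, -2))
  vals <- fe(X)
  gated <- predict(cl, X)$label == 0
  expect_true(all(vals[gated] == 0))
  expect_true(all(vals >= 0))
  expect_error(make_fitness(3, b2_model = b2m), "EHVI stage")
})
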