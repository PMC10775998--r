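test_that("counterfactual selection matches an independent brute-force filter", {
  # one Pareto sequence plus perturbed variants with controlled properties
  base <- paste0(strrep("E", 8), strrep("K", 8), strrep("W", 10))
  vars <- vapply(1:14, function(i) {
    ch <- strsplit(base, "")[[1]]
    set.seed(80 + i)
    ch[sample(length(ch), 2)] <- sample(AA_ALPHABET_TEST, 2, replace = TRUE)
    paste(ch, collapse = "")
  }, "")
  seqs <- unique(c(base, vars))
  set.seed(99)
  ds <- data.frame(id = paste0("s", seq_along(seqs)), sequence = seqs,
                   B2 = -40000 - 4000 * seq_along(seqs) +
                     rnorm(length(seqs), 0, 6000),
                   D = 2e-10 + rnorm(length(seqs), 0, 5e-11),
                   phase_sep = TRUE)
  sel <- select_counterfactuals(base, ds, front_seqs = base,
                                params = PARAMS, scaler = SCALER,
                                sim_threshold = 0.9,
                                dist_range = c(0.15, 0.3))
  # independent filter: recompute z-plane distances and cosines from scratch
  zb <- (ds$B2 - mean(ds$B2)) / sd(ds$B2)
  zd <- (ds$D - mean(ds$D)) / sd(ds$D)
  i0 <- which(ds$sequence == base)
  dist <- sqrt((zb - zb[i0])^2 + (zd - zd[i0])^2)
  X <- feature_matrix(ds$sequence, PARAMS, SCALER, warn_clamp = FALSE)
  cs <- as.numeric(X %*% X[i0, ] / (sqrt(rowSums(X^2)) * sqrt(sum(X[i0, ]^2))))
  want <- which(cs > 0.9 & dist >= 0.15 & dist <= 0.3)
  expect_setequal(sel$id, ds$id[want])
  # the Pareto sequence itself is excluded by the lower distance bound
  expect_false(base %in% sel$sequence)
  # selection is idempotent and order-independent
  o <- sample(nrow(ds))
  sel2 <- select_counterfactuals(base, ds[o, ], front_seqs = base,
                                 params = PARAMS, scaler = SCALER)
  expect_setequal(sel2$id, sel$id)
  expect_error(select_counterfactuals(base, ds[ds$phase_sep == FALSE, ]),
               "empty dataset")
})

test_that("average feature differences follow hand arithmetic and sign symmetry", {
  p1 <- strrep("W", 30)
  c1 <- paste0(strrep("W", 25), strrep("G", 5))
  # single counterfactual: plain difference of feature vectors
  d1 <- avg_feature_differences(p1, c1, PARAMS, SCALER)
  expect_equal(d1$mean_diff,
               unname(feature_vector(p1, PARAMS, SCALER) -
                        feature_vector(c1, PARAMS, SCALER)))
  expect_true(all(is.na(d1$se)))
  expect_equal(unique(d1$n), 1)

  # three counterfactuals: means and SEs match direct arithmetic
  cfs <- c(c1, paste0(strrep("G", 5), strrep("W", 25)), strrep("Y", 30))
  d3 <- avg_feature_differences(p1, cfs, PARAMS, SCALER)
  M <- t(vapply(cfs, function(s)
    feature_vector(p1, PARAMS, SCALER) - feature_vector(s, PARAMS, SCALER),
    numeric(30)))
  expect_equal(d3$mean_diff, unname(colMeans(M)))
  expect_equal(d3$se, unname(apply(M, 2, sd) / sqrt(3)))

  # swapping roles flips the sign of every mean difference
  dswap <- avg_feature_differences(c1, p1, PARAMS, SCALER)
  expect_equal(dswap$mean_diff, -d1$mean_diff)

  # counterfactuals symmetric about the Pareto point cancel
  lo <- paste0(strrep("W", 24), strrep("G", 6))
  hi <- strrep("W", 30)
  mid <- paste0(strrep("W", 27), strrep("G", 3))
  dsym <- avg_feature_differences(mid, c(lo, hi), PARAMS, SCALER)
  w_row <- dsym$feature == "comp_W"
  expect_equal(dsym$mean_diff[w_row], 0, tolerance = 1e-12)
})

test_that("similarity matrices are symmetric with unit diagonal and match pairwise cosines", {
  same <- rep(strrep("ADKW", 8), 3)
  sm <- similarity_matrices(same, PARAMS, SCALER)
  expect_true(all(abs(sm$composition - 1) < 1e-12))
  expect_true(all(abs(sm$descriptors - 1) < 1e-12))

  trio <- c(strrep("W", 25), paste0(strrep("E", 12), strrep("K", 13)),
            strrep("GS", 15))
  sm3 <- similarity_matrices(trio, PARAMS, SCALER)
  expect_equal(sm3$composition, t(sm3$composition))
  expect_equal(sm3$descriptors, t(sm3$descriptors))
  expect_equal(diag(sm3$composition), rep(1, 3))
  fv <- lapply(trio, feature_vector, params = PARAMS, scaler = SCALER)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(sm3$composition[i, j],
                 if (i == j) 1 else
                   cosine_similarity(fv[[i]], fv[[j]], "composition"),
                 tolerance = 1e-12)
    expect_equal(sm3$descriptors[i, j],
                 if (i == j) 1 else
                   cosine_similarity(fv[[i]], fv[[j]], "descriptors"),
                 tolerance = 1e-12)
  }
  expect_error(similarity_matrices(trio[1], PARAMS, SCALER))
})

test_that("the report runs over a converged small campaign", {
  seeds <- generate_disprot_like(40, seed = 82)
  orc <- make_toy_oracle(oracle_config(), PARAMS)
  cfg <- al_config(n_iterations = 3,
                   ga = ga_config(n_trials = 6, n_children = 6, n_steps = 30),
                   ntree = 101, gp_maxit = 30)
  st <- run_active_learning(seeds, orc, cfg, PARAMS, SCALER, master_seed = 83)
  rep_ <- counterfactual_report(st, dist_range = c(0.05, 0.6),
                                sim_threshold = 0.5)
  if (!is.null(rep_)) {
    expect_true(all(rep_$n >= 1))
    expect_true(all(rep_$pareto_id %in% al_archive(st)$points$id))
  }
})
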