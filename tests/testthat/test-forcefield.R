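test_that("packaged parameter table loads with the documented globals", {
  p <- load_parameter_table()
  expect_equal(nrow(p$residues), 20)
  expect_setequal(p$residues$residue,
                  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                    "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  expect_equal(p$bond_k, 10)
  expect_equal(p$bond_b0, 3.82)
  expect_equal(p$epsilon, 0.2)
  expect_equal(p$dielectric, 80)
  expect_equal(p$debye_kappa, 10)
  # residue invariants
  expect_true(all(p$residues$sigma > 0))
  expect_true(all(p$residues$mass > 0))
  expect_true(all(p$residues$lambda >= 0 & p$residues$lambda <= 1))
  expect_true(all(p$residues$charge %in% c(-1, 0, 1)))
  expect_equal(p$residues["H", "charge"], 0)   # neutral histidine default
  expect_equal(trunc(mean(p$residues$mass)), 118)
})

test_that("parameter validation names the offending residue", {
  p <- load_parameter_table()
  tab <- p$residues
  tmp <- tempfile(fileext = ".tsv")

  write.table(tab[tab$residue != "W", ], tmp, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(load_parameter_table(tmp), "missing residue.*W")

  tab2 <- tab; tab2["G", "sigma"] <- -1
  write.table(tab2, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(load_parameter_table(tmp), "sigma.*G")

  writeLines(c("residue\tnothing", "A\t1"), tmp)
  expect_error(load_parameter_table(tmp), "malformed")

  expect_error(load_parameter_table("/nonexistent/params.tsv"), "not found")
})

test_that("bonded energy is a harmonic well at b0", {
  p <- load_parameter_table()
  expect_equal(bonded_energy(3.82, p), 0)
  expect_equal(bonded_energy(4.82, p), 10)
  expect_equal(bonded_energy(2.82, p), bonded_energy(4.82, p))
  expect_error(bonded_energy(-1, p))
})

test_that("Ashbaugh-Hatch form is continuous at the crossover for all pairs", {
  p <- load_parameter_table()
  aa <- p$residues$residue
  for (i in seq_along(aa)) {
    for (j in i:length(aa)) {
      sig <- (p$residues[aa[i], "sigma"] + p$residues[aa[j], "sigma"]) / 2
      lam <- (p$residues[aa[i], "lambda"] + p$residues[aa[j], "lambda"]) / 2
      rc <- 2^(1 / 6) * sig
      lhs <- vdw_pair_energy(rc * (1 - 1e-12), aa[i], aa[j], p)
      rhs <- vdw_pair_energy(rc * (1 + 1e-12), aa[i], aa[j], p)
      expect_lt(abs(lhs - rhs), 1e-10)
      # the shared value at the crossover is -lambda_ij * epsilon
      expect_equal(vdw_pair_energy(rc, aa[i], aa[j], p), -lam * p$epsilon,
                   tolerance = 1e-9)
    }
  }
})

test_that("vdW limits: lambda = 1 gives the pure LJ tail, value (1-lam)*eps at r = sigma", {
  p <- load_parameter_table()
  # W-W has lambda_ij = 1: beyond the crossover the energy is plain LJ
  sig <- p$residues["W", "sigma"]
  r <- seq(sig * 1.2, 30, length.out = 50)
  lj <- 4 * p$epsilon * ((sig / r)^12 - (sig / r)^6)
  expect_equal(vdw_pair_energy(r, "W", "W", p), lj, tolerance = 1e-12)
  # at r = sigma_ij the LJ term vanishes, leaving (1 - lambda_ij) * epsilon
  for (pair in list(c("G", "G"), c("E", "F"), c("K", "Y"))) {
    sigij <- (p$residues[pair[1], "sigma"] + p$residues[pair[2], "sigma"]) / 2
    lamij <- (p$residues[pair[1], "lambda"] + p$residues[pair[2], "lambda"]) / 2
    expect_equal(vdw_pair_energy(sigij, pair[1], pair[2], p),
                 (1 - lamij) * p$epsilon, tolerance = 1e-12)
  }
})

test_that("a lambda = 0 pair is purely repulsive", {
  p <- load_parameter_table()
  p$residues[c("G", "A"), "lambda"] <- 0    # neutral residues forced athermal
  r <- seq(2, 40, by = 0.05)
  u <- vdw_pair_energy(r, "G", "A", p)
  expect_true(all(u >= -1e-14))
  rc <- 2^(1 / 6) * (p$residues["G", "sigma"] + p$residues["A", "sigma"]) / 2
  expect_equal(vdw_pair_energy(rc, "G", "A", p), 0, tolerance = 1e-12)
  expect_true(all(abs(u[r > rc]) < 1e-14))
})

test_that("screened electrostatics: neutral pairs, screening identity, antisymmetry, decay", {
  p <- load_parameter_table()
  r <- c(3, 5, 10, 25)
  expect_equal(elec_pair_energy(r, "G", "K", p), rep(0, 4))
  # at r = kappa the energy is prefactor/(dielectric*kappa) * exp(-1)
  kap <- p$debye_kappa
  expect_equal(elec_pair_energy(kap, "K", "R", p),
               p$coulomb_const / (p$dielectric * kap) * exp(-1))
  # like vs unlike charges: equal magnitude, opposite sign
  expect_equal(elec_pair_energy(r, "E", "K", p), -elec_pair_energy(r, "E", "D", p))
  expect_lt(elec_pair_energy(5, "E", "K", p), 0)
  # |phi * r| strictly decreasing (decays faster than 1/r)
  rr <- seq(1, 60, by = 0.5)
  mod <- abs(elec_pair_energy(rr, "E", "E", p) * rr)
  expect_true(all(diff(mod) < 0))
})

test_that("pair energies are symmetric under residue exchange and vanish at infinity", {
  p <- load_parameter_table()
  set.seed(42)
  pairs <- replicate(25, sample(p$residues$residue, 2), simplify = FALSE)
  r <- c(4, 6.5, 12)
  for (pr in pairs) {
    expect_equal(total_pair_potential(r, pr[1], pr[2], p),
                 total_pair_potential(r, pr[2], pr[1], p))
  }
  expect_lt(max(abs(vapply(pairs, function(pr)
    total_pair_potential(100, pr[1], pr[2], p), numeric(1)))), 2e-6)
  # neutral pair: total potential equals the vdW term alone
  expect_equal(total_pair_potential(r, "G", "G", p),
               vdw_pair_energy(r, "G", "G", p))
  expect_error(total_pair_potential(5, "X", "G", p), "unknown residue")
})

test_that("Debye length at 0.1 M, dielectric 80, 300 K rounds to 1 nm", {
  ld <- debye_length(0.1, 80, 300)
  expect_equal(round(ld), 1)
  expect_equal(ld, 0.974, tolerance = 1e-3)
  # scales as I^(-1/2)
  expect_equal(debye_length(0.4, 80, 300), ld / 2, tolerance = 1e-12)
})
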