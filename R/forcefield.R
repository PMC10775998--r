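#' Load and validate a coarse-grained residue parameter table
#'
#' Reads a per-residue parameter table for the HPS coarse-grained IDP model:
#' hydropathy scale factor \eqn{\lambda_i \in [0,1]}, van der Waals diameter
#' \eqn{\sigma_i} (Angstrom), charge \eqn{q_i} (elementary charges) and mass
#' \eqn{m_i} (g/mol) for each of the 20 canonical amino acids, together with
#' the global force-field constants (harmonic bond constant and length,
#' Lennard-Jones epsilon, solvent dielectric, Debye screening length).
#'
#' The packaged default is the published HPS-Urry parameter set. Users may
#' supply their own table in the same layout (TSV with header
#' \code{residue lambda sigma charge mass}) plus an optional YAML file of
#' globals.
#'
#' @param source path to a TSV parameter table, or \code{"default"} for the
#'   packaged set.
#' @param globals path to a YAML file of global constants, or \code{"default"}.
#' @param his_charge charge assigned to histidine (default 0, neutral at
#'   pH 7 per the parameter set's convention).
#' @return an object of class \code{idp_params}: a list with \code{residues}
#'   (data.frame indexed by one-letter code) and the global constants.
#' @export
load_parameter_table <- function(source = "default", globals = "default",
                                 his_charge = 0) {
  path <- if (identical(source, "default")) {
    system.file("extdata", "hps_urry_params.tsv", package = "idpal")
  } else source
  if (!nzchar(path) || !file.exists(path)) {
    stop("parameter table not found: ", source)
  }
  tab <- tryCatch(read.delim(path, stringsAsFactors = FALSE),
                  error = function(e) stop("malformed parameter file: ",
                                           conditionMessage(e)))
  need <- c("residue", "lambda", "sigma", "charge", "mass")
  if (!all(need %in% names(tab))) {
    stop("malformed parameter file: expected columns ",
         paste(need, collapse = " "))
  }
  missing <- setdiff(AA_ALPHABET, tab$residue)
  if (length(missing) > 0) {
    stop("missing residue: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(tab$residue, AA_ALPHABET)
  if (length(extra) > 0) {
    stop("unknown residue code in table: ", paste(extra, collapse = ", "))
  }
  tab <- tab[match(AA_ALPHABET, tab$residue), ]
  rownames(tab) <- tab$residue
  bad_sigma <- tab$residue[!is.finite(tab$sigma) | tab$sigma <= 0]
  if (length(bad_sigma) > 0) {
    stop("non-physical value (sigma <= 0) for residue ",
         paste(bad_sigma, collapse = ", "))
  }
  bad_mass <- tab$residue[!is.finite(tab$mass) | tab$mass <= 0]
  if (length(bad_mass) > 0) {
    stop("non-physical value (mass <= 0) for residue ",
         paste(bad_mass, collapse = ", "))
  }
  bad_lambda <- tab$residue[!is.finite(tab$lambda) | tab$lambda < 0 |
                              tab$lambda > 1]
  if (length(bad_lambda) > 0) {
    stop("non-physical value (lambda outside [0,1]) for residue ",
         paste(bad_lambda, collapse = ", "))
  }
  tab["H", "charge"] <- his_charge
  gpath <- if (identical(globals, "default")) {
    system.file("extdata", "ff_globals.yaml", package = "idpal")
  } else globals
  gl <- yaml::read_yaml(gpath)
  obj <- list(residues = tab,
              bond_k = gl$bond_k, bond_b0 = gl$bond_b0,
              epsilon = gl$epsilon, dielectric = gl$dielectric,
              debye_kappa = gl$debye_kappa, b0_ref = gl$b0_ref,
              coulomb_const = gl$coulomb_const,
              temperature = gl$temperature)
  class(obj) <- "idp_params"
  obj
}

#' @export
print.idp_params <- function(x, ...) {
  cat("HPS coarse-grained IDP parameter table (20 residues)\n")
  cat(sprintf("  bond: k = %g kcal/(mol A^2), b0 = %g A\n", x$bond_k, x$bond_b0))
  cat(sprintf("  epsilon = %g kcal/mol, dielectric = %g, kappa = %g A\n",
              x$epsilon, x$dielectric, x$debye_kappa))
  invisible(x)
}

.check_residues <- function(res, params) {
  bad <- setdiff(res, AA_ALPHABET)
  if (length(bad) > 0) stop("unknown residue code: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Harmonic bonded energy
#'
#' \eqn{k_b (r - b_0)^2} between consecutive residues.
#'
#' @param r bond length in Angstrom (vectorized).
#' @param params an \code{idp_params} object.
#' @return energy in kcal/mol.
#' @export
bonded_energy <- function(r, params = load_parameter_table()) {
  stopifnot(all(r > 0))
  params$bond_k * (r - params$bond_b0)^2
}

#' Ashbaugh-Hatch van der Waals pair energy
#'
#' Piecewise hydropathy-scaled Lennard-Jones interaction: for
#' \eqn{r \le 2^{1/6}\sigma_{ij}} the full LJ potential shifted by
#' \eqn{(1-\lambda_{ij})\epsilon}, beyond the minimum the LJ tail scaled by
#' \eqn{\lambda_{ij}}. Mixing rules are arithmetic:
#' \eqn{\lambda_{ij} = (\lambda_i+\lambda_j)/2},
#' \eqn{\sigma_{ij} = (\sigma_i+\sigma_j)/2}.
#'
#' @param r separation in Angstrom (vectorized).
#' @param res_i,res_j one-letter residue codes.
#' @param params an \code{idp_params} object.
#' @return energy in kcal/mol.
#' @export
vdw_pair_energy <- function(r, res_i, res_j, params = load_parameter_table()) {
  stopifnot(all(r > 0))
  .check_residues(c(res_i, res_j), params)
  tab <- params$residues
  lam <- (tab[res_i, "lambda"] + tab[res_j, "lambda"]) / 2
  sig <- (tab[res_i, "sigma"] + tab[res_j, "sigma"]) / 2
  eps <- params$epsilon
  sr6 <- (sig / r)^6
  lj <- 4 * eps * (sr6^2 - sr6)
  rc <- 2^(1 / 6) * sig
  ifelse(r <= rc, lj + (1 - lam) * eps, lam * lj)
}

#' Screened (Debye-Hueckel) electrostatic pair energy
#'
#' \eqn{\phi_{el}(r) = C\, q_i q_j / (D r)\, e^{-r/\kappa}} with the Coulomb
#' prefactor \eqn{C = e^2/(4\pi\epsilon_0)} folded into a single constant
#' (332.0637 kcal A/mol) so energies are in kcal/mol with r in Angstrom.
#'
#' @inheritParams vdw_pair_energy
#' @return energy in kcal/mol.
#' @export
elec_pair_energy <- function(r, res_i, res_j, params = load_parameter_table()) {
  stopifnot(all(r > 0))
  .check_residues(c(res_i, res_j), params)
  tab <- params$residues
  qq <- tab[res_i, "charge"] * tab[res_j, "charge"]
  if (all(qq == 0)) return(rep(0, max(length(r), length(qq))))
  params$coulomb_const * qq / (params$dielectric * r) * exp(-r / params$debye_kappa)
}

#' Total nonbonded pair potential (vdW + screened electrostatics)
#'
#' @inheritParams vdw_pair_energy
#' @return energy in kcal/mol.
#' @export
total_pair_potential <- function(r, res_i, res_j, params = load_parameter_table()) {
  vdw_pair_energy(r, res_i, res_j, params) +
    elec_pair_energy(r, res_i, res_j, params)
}

#' Debye screening length of a 1:1 electrolyte
#'
#' \eqn{\lambda_D = \sqrt{\epsilon_0 \epsilon_r k_B T / (2 N_A e^2 I)}} with
#' the ionic strength \eqn{I} in mol/L. At 0.1 M, dielectric 80 and 300 K this
#' is 0.97 nm, the 1 nm screening length used by the CG model.
#'
#' @param ionic_strength mol/L.
#' @param dielectric relative permittivity.
#' @param temperature K.
#' @return Debye length in nm.
#' @export
debye_length <- function(ionic_strength = 0.1, dielectric = 80,
                         temperature = 300) {
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  NA_ <- 6.02214076e23       # 1/mol
  e <- 1.602176634e-19       # C
  I_m3 <- ionic_strength * 1000 * NA_   # ions per m^3 per species
  lam <- sqrt(eps0 * dielectric * kB * temperature / (2 * I_m3 * e^2))
  lam * 1e9
}

# Pair second-virial integrals b2(a,b) = 2*pi * int r^2 (1 - exp(-beta*phi_ab))
# for all 210 residue-type pairs of the single-bead potential; cached per
# parameter table. Used by the B2_MF feature.
.b2mf_cache <- new.env(parent = emptyenv())

pair_b2_matrix <- function(params, r_max = 100, dr = 0.2) {
  key <- paste0(paste(params$residues$lambda, collapse = ","), "|",
                paste(params$residues$charge, collapse = ","), "|",
                params$epsilon, "|", params$debye_kappa, "|",
                params$temperature, "|", r_max, "|", dr)
  key <- as.character(sum(utf8ToInt(key) * seq_along(utf8ToInt(key))))
  if (!is.null(.b2mf_cache[[key]])) return(.b2mf_cache[[key]])
  beta <- 1 / (KB_KCAL * params$temperature)
  r <- seq(dr, r_max, by = dr)
  m <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (i in seq_len(20)) {
    for (j in i:20) {
      u <- total_pair_potential(r, AA_ALPHABET[i], AA_ALPHABET[j], params)
      integrand <- r^2 * (1 - exp(-beta * u))
      integrand[!is.finite(integrand)] <- r[!is.finite(integrand)]^2
      # hard-core contribution below the first grid point
      core <- dr^3 / 3
      val <- 2 * pi * (core + trapz(r, integrand))
      m[i, j] <- m[j, i] <- val
    }
  }
  .b2mf_cache[[key]] <- m
  m
}

# composite trapezoid rule on a (possibly nonuniform) grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}
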