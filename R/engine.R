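#' Register a gas-phase potential
#'
#' A gas-phase potential is a callable contract: given an [ml_region()] it
#' returns `list(energy, gradient)` with energy in kcal/mol and the gradient
#' (dE/dR) in kcal/mol/A. At registration the gradient is validated against
#' central finite differences on probe geometries.
#'
#' @param energy_fun function(region) -> list(energy, gradient).
#' @param name short name for reports.
#' @param elements element coverage (character vector).
#' @param probe optional list of [ml_region()] probe geometries for
#'   validation.
#' @param validate check gradients against finite differences (1e-6
#'   relative) at registration.
#' @param notes free-text validity notes.
#' @return an object of class `gas_phase_potential`.
#' @export
gas_phase_potential <- function(energy_fun, name, elements, probe = NULL,
                                validate = TRUE, notes = "") {
  obj <- structure(list(fun = energy_fun, name = name, elements = elements,
                        notes = notes),
                   class = "gas_phase_potential")
  if (validate && !is.null(probe)) {
    for (region in probe) {
      out <- energy_fun(region)
      fd <- .fd_gradient(function(r) energy_fun(r)$energy, region,
                         step = 1e-5)
      scale <- max(abs(fd), 1)
      if (max(abs(out$gradient - fd)) > 1e-6 * scale) {
        stop("gas-phase potential '", name, "' failed gradient validation",
             call. = FALSE)
      }
    }
  }
  obj
}

#' @export
print.gas_phase_potential <- function(x, ...) {
  cat("gas_phase_potential '", x$name, "' covering ",
      paste(x$elements, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Evaluate a gas-phase potential
#' @param gas a [gas_phase_potential()].
#' @param region an [ml_region()].
#' @return list(energy, gradient) in kcal/mol and kcal/mol/A.
#' @export
evaluate_gas <- function(gas, region) {
  unknown <- setdiff(unique(region$elements), gas$elements)
  if (length(unknown) > 0) {
    stop("gas potential '", gas$name, "' does not cover element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gas$fun(region)
}

# Central finite-difference gradient of f(region) wrt region coordinates
# (step in angstrom); returns an n x 3 matrix.
.fd_gradient <- function(f, region, step = 1e-4) {
  coords <- region$coordinates
  g <- matrix(0, nrow(coords), 3)
  for (i in seq_len(nrow(coords))) {
    for (k in 1:3) {
      rp <- region; rp$coordinates[i, k] <- coords[i, k] + step
      rm <- region; rm$coordinates[i, k] <- coords[i, k] - step
      g[i, k] <- (f(rp) - f(rm)) / (2 * step)
    }
  }
  g
}

#' Embedding variant selector
#'
#' `emle` uses all four energy components; `mechanical` removes the induced
#' component (conformation-dependent charges but no polarization);
#' `mm_fixed` additionally replaces the static component by a plain Coulomb
#' interaction with a named fixed charge set (e.g. reactant-derived `q_R` or
#' product-derived `q_P`).
#'
#' @param kind `"emle"`, `"mechanical"` or `"mm_fixed"`.
#' @param fixed_charges per-ML-atom charges (required for `mm_fixed`).
#' @param charge_set_name label for the fixed charge set (e.g. `"q_R"`).
#' @return an object of class `embedding_variant`.
#' @export
embedding_variant <- function(kind = c("emle", "mechanical", "mm_fixed"),
                              fixed_charges = NULL, charge_set_name = NULL) {
  kind <- match.arg(kind)
  if (kind == "mm_fixed" && is.null(fixed_charges)) {
    stop("mm_fixed requires a fixed charge set", call. = FALSE)
  }
  structure(list(kind = kind, fixed_charges = fixed_charges,
                 charge_set_name = charge_set_name %||% ""),
            class = "embedding_variant")
}

# 12-6 Lennard-Jones ML-MM interaction (Lorentz-Berthelot combining),
# angstrom / kcal/mol, with analytic forces.
.lj_ml_mm <- function(region, env, ml_lj, gradient = FALSE) {
  nml <- n_atoms(region)
  nmm <- nrow(env$positions)
  zero <- list(energy = 0, forces_ml = matrix(0, nml, 3),
               forces_mm = matrix(0, nmm, 3))
  if (is.null(ml_lj) || all(env$lj_epsilon == 0)) return(zero)
  sig <- outer(ml_lj$sigma, env$lj_sigma, "+") / 2
  eps <- sqrt(outer(ml_lj$epsilon, env$lj_epsilon))
  dx <- outer(region$coordinates[, 1], env$positions[, 1], "-")
  dy <- outer(region$coordinates[, 2], env$positions[, 2], "-")
  dz <- outer(region$coordinates[, 3], env$positions[, 3], "-")
  d2 <- dx^2 + dy^2 + dz^2
  sr6 <- (sig^2 / d2)^3
  energy <- sum(4 * eps * (sr6^2 - sr6))
  if (!gradient) return(list(energy = energy))
  # dE/dd * (1/d) = -24 eps (2 sr12 - sr6) / d^2
  coef <- -24 * eps * (2 * sr6^2 - sr6) / d2
  fml <- -cbind(rowSums(coef * dx), rowSums(coef * dy), rowSums(coef * dz))
  fmm <- cbind(colSums(coef * dx), colSums(coef * dy), colSums(coef * dz))
  list(energy = energy, forces_ml = fml, forces_mm = fmm)
}

#' Total ML/MM energy with a chosen embedding variant
#'
#' Assembles `E_total = E_gas + E_static + E_induced + E_MM` (kcal/mol).
#' The MM term covers ML-MM Lennard-Jones interactions only; MM-internal
#' nonbonded energy is excluded (constant for a frozen environment).
#'
#' Force modes: `"none"` (energies only), `"fast"` (analytic forces with
#' density parameters and polarizabilities frozen at their predicted
#' values), `"fd"` (central finite differences of the full energy, step
#' 1e-3 bohr, including the geometry response of the predicted parameters;
#' this mode defines force correctness).
#'
#' @param region an [ml_region()].
#' @param env an [mm_environment()] or `NULL` for gas phase.
#' @param gas a [gas_phase_potential()].
#' @param static a [static_model()] or ground-truth backend (ignored for
#'   `mm_fixed`).
#' @param pol a [polarizability_model()] or ground-truth backend (used by
#'   `emle` only).
#' @param variant an [embedding_variant()].
#' @param ml_lj optional `list(sigma, epsilon)` per ML atom for the LJ term.
#' @param force_mode `"none"`, `"fast"` or `"fd"`.
#' @return an [energy_decomposition()]; with forces when requested.
#' @export
total_energy <- function(region, env, gas, static = NULL, pol = NULL,
                         variant = embedding_variant("emle"),
                         ml_lj = NULL, force_mode = c("none", "fast", "fd")) {
  force_mode <- match.arg(force_mode)
  nml <- n_atoms(region)
  g <- evaluate_gas(gas, region)
  if (is.null(env) || nrow(env$positions) == 0) {
    dec <- energy_decomposition(g$energy, 0, 0, 0,
                                forces_ml = if (force_mode != "none") -g$gradient,
                                forces_mm = NULL)
    return(dec)
  }
  want_grad <- force_mode == "fast"
  if (variant$kind == "mm_fixed") {
    if (length(variant$fixed_charges) != nml) {
      stop("fixed charge set length does not match ML region", call. = FALSE)
    }
    st <- mm_embedding_energy(variant$fixed_charges, region, env,
                              gradient = want_grad)
    ind <- NULL
  } else {
    density <- predict_density(static, region)
    st <- static_energy(density, region, env, gradient = want_grad)
    ind <- if (variant$kind == "emle") {
      alphas <- atomic_polarizabilities(pol, density, region)
      solve_induction(alphas, region, env,
                      damping_a = pol$thole_damping_a, gradient = want_grad)
    }
  }
  e_static_h <- if (want_grad) st$energy else st
  e_ind_h <- if (is.null(ind)) 0 else ind$e_induced
  lj <- .lj_ml_mm(region, env, ml_lj, gradient = want_grad)
  dec <- energy_decomposition(
    g$energy,
    convert_units(e_static_h, "hartree", "kcal/mol"),
    convert_units(e_ind_h, "hartree", "kcal/mol"),
    lj$energy
  )
  if (force_mode == "none") return(dec)
  if (force_mode == "fast") {
    h2k <- HARTREE_TO_KCALMOL / BOHR_TO_ANGSTROM  # hartree/bohr -> kcal/mol/A
    fml <- -g$gradient + st$forces_ml * h2k + lj$forces_ml
    fmm <- st$forces_mm * h2k + lj$forces_mm
    if (!is.null(ind)) {
      fml <- fml + ind$forces_ml * h2k
      fmm <- fmm + ind$forces_mm * h2k
    }
    dec$forces_ml <- fml
    dec$forces_mm <- fmm
    return(dec)
  }
  # fd mode: central differences of the full energy, step 1e-3 bohr,
  # including parameter response.
  step <- 1e-3 * BOHR_TO_ANGSTROM
  etot <- function(r, e) {
    total_energy(r, e, gas, static, pol, variant, ml_lj,
                 force_mode = "none")$e_total
  }
  dec$forces_ml <- -.fd_gradient(function(r) etot(r, env), region, step)
  fmm <- matrix(0, nrow(env$positions), 3)
  for (j in seq_len(nrow(env$positions))) {
    for (k in 1:3) {
      ep <- env; ep$positions[j, k] <- env$positions[j, k] + step
      em <- env; em$positions[j, k] <- env$positions[j, k] - step
      fmm[j, k] <- -(etot(region, ep) - etot(region, em)) / (2 * step)
    }
  }
  dec$forces_mm <- fmm
  dec
}

#' Build an ML-region force field from an embedding setup
#'
#' Convenience wrapper returning the `function(region) -> list(energy,
#' forces)` contract used by [run_langevin()] and [run_umbrella()]:
#' energies and fast-path analytic forces from [total_energy()] for a fixed
#' MM environment.
#'
#' @inheritParams total_energy
#' @param restraints optional list of [restraint()] objects added to the
#'   energy and forces (e.g. pocket anchors or the one-sided bond guard).
#' @param param_response_rc optional [reaction_coordinate()]. The fast
#'   force path freezes the predicted density parameters and
#'   polarizabilities; when the parameters change strongly along a reaction
#'   coordinate (large charge rearrangement), the missing
#'   parameter-response force matters for sampling. With this argument the
#'   response is restored along the given RC by a central-difference
#'   chain rule: the embedding energy is re-evaluated at the same geometry
#'   with parameters predicted at RC-displaced geometries, and the
#'   resulting dE/dxi is projected onto the RC gradient. Exact when the
#'   parameters depend on geometry only through the RC (as for the
#'   synthetic ground truth); ignored for the `mm_fixed` variant, whose
#'   charges have no geometry response.
#' @return a force function over the ML region.
#' @export
embedding_force_fun <- function(env, gas, static = NULL, pol = NULL,
                                variant = embedding_variant("emle"),
                                ml_lj = NULL, restraints = list(),
                                param_response_rc = NULL) {
  function(region) {
    dec <- total_energy(region, env, gas, static, pol, variant,
                        ml_lj = ml_lj, force_mode = "fast")
    energy <- dec$e_total
    forces <- dec$forces_ml
    if (!is.null(param_response_rc) && variant$kind != "mm_fixed" &&
        !is.null(env) && nrow(env$positions) > 0) {
      forces <- forces + .param_response_force(region, env, static, pol,
                                               variant, param_response_rc)
    }
    for (res in restraints) {
      re <- restraint_energy(res, region)
      energy <- energy + re$energy
      forces <- forces + re$forces
    }
    list(energy = energy, forces = forces, decomposition = dec)
  }
}

# Embedding energy (static + induced, kcal/mol) at geometry `region` using
# parameters predicted at geometry `at`.
.embed_energy_at <- function(region, at, env, static, pol, variant) {
  density <- predict_density(static, at)
  e <- static_energy(density, region, env)
  if (variant$kind == "emle") {
    alphas <- atomic_polarizabilities(pol, density, at)
    e <- e + solve_induction(alphas, region, env,
                             damping_a = pol$thole_damping_a)$e_induced
  }
  convert_units(e, "hartree", "kcal/mol")
}

# RC-projected parameter-response force (kcal/mol/A).
.param_response_force <- function(region, env, static, pol, variant, rc,
                                  h = 1e-3) {
  ev <- evaluate_rc(rc, region, gradient = TRUE)
  g2 <- sum(ev$gradient^2)
  if (g2 < 1e-12) return(0)
  rp <- region; rp$coordinates <- rp$coordinates + (h / g2) * ev$gradient
  rm <- region; rm$coordinates <- rm$coordinates - (h / g2) * ev$gradient
  de_dxi <- (.embed_energy_at(region, rp, env, static, pol, variant) -
               .embed_energy_at(region, rm, env, static, pol, variant)) /
    (2 * h)
  -de_dxi * ev$gradient
}

#' Reference induced energy from total, gas and static components
#'
#' `E_induced = E_ref_total - (E_gas + E_static)`: the induction energy is
#' whatever part of the full embedded energy the gas and static terms do not
#' account for. Pure arithmetic; vectorized.
#'
#' @param e_ref_total full embedded reference energies.
#' @param e_gas,e_static gas-phase and static components.
#' @return induced energies.
#' @export
induced_from_reference <- function(e_ref_total, e_gas, e_static) {
  e_ref_total - (e_gas + e_static)
}

#' Define a restraint
#'
#' Restraint energies follow the MD-engine convention `K * (delta)^2`
#' without the 1/2 factor (switchable via `half_convention`): a
#' `harmonic_rc` restraint is `K (xi - xi0)^2` on a reaction coordinate; a
#' `one_sided_distance` restraint is `K (d - threshold)^2` applied only when
#' the distance drops below the threshold (used e.g. to prevent formation of
#' an unphysical bond).
#'
#' @param kind `"harmonic_rc"`, `"one_sided_distance"` or `"position"` (an
#'   isotropic harmonic anchor holding one atom near a reference point,
#'   e.g. to keep a substrate in a binding pocket).
#' @param rc a [reaction_coordinate()] (harmonic_rc) .
#' @param pair length-2 atom-label vector (one_sided_distance), or a single
#'   atom label (position).
#' @param target target RC value xi0 (angstrom), or the reference 3-vector
#'   (position).
#' @param force_constant K >= 0 (kcal/mol/A^2).
#' @param threshold activation threshold (angstrom, one-sided only).
#' @param half_convention if `TRUE`, use `K/2 * delta^2` instead.
#' @return an object of class `restraint`.
#' @export
restraint <- function(kind = c("harmonic_rc", "one_sided_distance",
                               "position"),
                      rc = NULL, pair = NULL, target = NULL,
                      force_constant = 100, threshold = NULL,
                      half_convention = FALSE) {
  kind <- match.arg(kind)
  if (force_constant < 0) stop("force constant must be >= 0", call. = FALSE)
  if (kind == "harmonic_rc" && (is.null(rc) || is.null(target))) {
    stop("harmonic_rc needs rc and target", call. = FALSE)
  }
  if (kind == "one_sided_distance" && (is.null(pair) || is.null(threshold))) {
    stop("one_sided_distance needs pair and threshold", call. = FALSE)
  }
  if (kind == "position" &&
      (is.null(pair) || length(target) != 3)) {
    stop("position needs one atom label and a 3-vector target", call. = FALSE)
  }
  structure(list(kind = kind, rc = rc, pair = pair, target = target,
                 force_constant = force_constant, threshold = threshold,
                 half_convention = half_convention),
            class = "restraint")
}

#' Restraint energy and forces
#'
#' @param res a [restraint()].
#' @param region an [ml_region()].
#' @return list(energy, forces) in kcal/mol and kcal/mol/A.
#' @export
restraint_energy <- function(res, region) {
  pref <- if (res$half_convention) 0.5 else 1.0
  n <- n_atoms(region)
  if (res$kind == "harmonic_rc") {
    ev <- evaluate_rc(res$rc, region, gradient = TRUE)
    delta <- ev$value - res$target
    energy <- pref * res$force_constant * delta^2
    forces <- -2 * pref * res$force_constant * delta * ev$gradient
    return(list(energy = energy, forces = forces, value = ev$value))
  }
  if (res$kind == "position") {
    idx <- .resolve_labels(region, res$pair[1])
    dvec <- region$coordinates[idx, ] - res$target
    energy <- pref * res$force_constant * sum(dvec^2)
    forces <- matrix(0, n, 3)
    forces[idx, ] <- -2 * pref * res$force_constant * dvec
    return(list(energy = energy, forces = forces,
                value = sqrt(sum(dvec^2))))
  }
  idx <- .resolve_labels(region, res$pair)
  dvec <- region$coordinates[idx[1], ] - region$coordinates[idx[2], ]
  d <- sqrt(sum(dvec^2))
  forces <- matrix(0, n, 3)
  energy <- 0
  if (d < res$threshold) {
    delta <- d - res$threshold
    energy <- pref * res$force_constant * delta^2
    g <- 2 * pref * res$force_constant * delta * dvec / d
    forces[idx[1], ] <- -g
    forces[idx[2], ] <- g
  }
  list(energy = energy, forces = forces, value = d)
}

# Standard atomic masses (amu).
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

#' Langevin (BAOAB) dynamics over the ML region
#'
#' Integrates the ML atoms with the BAOAB splitting of Langevin dynamics at
#' fixed temperature; the MM environment stays frozen. With zero temperature
#' and zero friction the scheme reduces to velocity Verlet. Deterministic
#' given the seed.
#'
#' @param force_fun function(region) -> list with `energy` (kcal/mol) and
#'   `forces` (kcal/mol/A, n x 3).
#' @param region starting [ml_region()].
#' @param dt_fs timestep (fs).
#' @param n_steps number of steps.
#' @param temperature kelvin.
#' @param friction_fs friction (1/fs); 0 disables the thermostat.
#' @param seed integer RNG seed.
#' @param masses optional per-atom masses (amu); element defaults otherwise.
#' @param velocities optional initial velocities (A/fs); Maxwell-Boltzmann
#'   draw (or zeros at T = 0) otherwise.
#' @param record function(step, region, velocities, energy) called after
#'   every step, or `NULL`.
#' @return list with final `region`, `velocities`, and `energies` (per-step
#'   potential energies).
#' @export
run_langevin <- function(force_fun, region, dt_fs, n_steps,
                         temperature = 300, friction_fs = 0.01,
                         seed = 1L, masses = NULL, velocities = NULL,
                         record = NULL) {
  n <- n_atoms(region)
  if (is.null(masses)) {
    masses <- unname(ATOMIC_MASSES[region$elements])
    if (anyNA(masses)) stop("no default mass for some element", call. = FALSE)
  }
  set.seed(as.integer(seed))
  kt <- KB_KCALMOL * temperature
  sig_v <- sqrt(kt * ACC_KCALMOL_A_AMU / masses)  # A/fs thermal width
  if (is.null(velocities)) {
    velocities <- if (temperature > 0) {
      matrix(stats::rnorm(3 * n), n, 3) * sig_v
    } else matrix(0, n, 3)
  }
  c1 <- exp(-friction_fs * dt_fs)
  c2 <- sqrt(1 - c1^2)
  f <- force_fun(region)
  acc <- f$forces * ACC_KCALMOL_A_AMU / masses
  energies <- numeric(n_steps)
  for (step in seq_len(n_steps)) {
    velocities <- velocities + 0.5 * dt_fs * acc
    region$coordinates <- region$coordinates + 0.5 * dt_fs * velocities
    if (friction_fs > 0) {
      velocities <- c1 * velocities +
        c2 * matrix(stats::rnorm(3 * n), n, 3) * sig_v
    }
    region$coordinates <- region$coordinates + 0.5 * dt_fs * velocities
    f <- force_fun(region)
    acc <- f$forces * ACC_KCALMOL_A_AMU / masses
    velocities <- velocities + 0.5 * dt_fs * acc
    energies[step] <- f$energy
    if (!is.null(record)) record(step, region, velocities, f$energy)
  }
  list(region = region, velocities = velocities, energies = energies)
}
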