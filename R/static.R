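#' Atomic density parameters of the ML region
#'
#' The ML-region electron density is modelled as a sum of spherical Slater
#' valence clouds on top of point cores (the MBIS picture): atom `i` carries
#' a net charge `q_i`, a valence population `N_i` (electrons in the cloud),
#' a valence width `s_i` (bohr) and a density-derived volume `v_i` (bohr^3).
#'
#' @param charges per-atom net charges (e).
#' @param widths per-atom Slater valence widths (bohr, > 0).
#' @param valence_populations per-atom valence electron counts (e).
#' @param volumes per-atom volumes (bohr^3, > 0).
#' @param total_charge optional; when given, `sum(charges)` must match to
#'   1e-10.
#' @return an object of class `density_parameters`.
#' @export
density_parameters <- function(charges, widths, valence_populations, volumes,
                               total_charge = NULL) {
  n <- length(charges)
  if (length(widths) != n || length(valence_populations) != n ||
      length(volumes) != n) {
    stop("per-atom arrays must have equal length", call. = FALSE)
  }
  if (any(widths <= 0)) stop("all widths must be positive", call. = FALSE)
  if (any(volumes <= 0)) stop("all volumes must be positive", call. = FALSE)
  if (!is.null(total_charge) &&
      abs(sum(charges) - total_charge) > 1e-10 * max(1, abs(total_charge))) {
    stop("charges sum to ", format(sum(charges), digits = 12),
         " but total charge is ", total_charge, call. = FALSE)
  }
  structure(list(charges = as.numeric(charges),
                 widths = as.numeric(widths),
                 valence_populations = as.numeric(valence_populations),
                 volumes = as.numeric(volumes)),
            class = "density_parameters")
}

# Element-default valence populations for the core/valence split.
DEFAULT_VALENCE <- c(H = 1, C = 4, N = 5, O = 6, S = 6)

.valence_for <- function(elements) {
  unknown <- setdiff(unique(elements), names(DEFAULT_VALENCE))
  if (length(unknown) > 0) {
    stop("no default valence population for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(DEFAULT_VALENCE[elements])
}

# Softplus-style positivity floor; approximately identity well above floor.
.softplus_floor <- function(x, floor, sharp = 50) {
  floor + log1p(exp(-abs(sharp * (x - floor)))) / sharp +
    pmax(x - floor, 0)
}

#' Electrostatic potential of a Slater-valence atom
#'
#' Point core of charge `q + N` plus a spherical Slater valence cloud of
#' charge `-N` and width `s`, `rho(r) = N exp(-r/s) / (8 pi s^3)`:
#' `V(d) = (q + N)/d - (N/d) * (1 - exp(-d/s) (1 + d/(2 s)))` (atomic
#' units). `V(d) -> q/d` for `d >> s`; the difference from `q/d` at short
#' range is the charge-penetration term, positive for a neutral atom.
#'
#' @param q net atomic charge (e).
#' @param n_val valence population (e).
#' @param s Slater width (bohr, > 0).
#' @param d distance (bohr, > 0); vectorized.
#' @return potential in atomic units (hartree / e).
#' @export
slater_potential <- function(q, n_val, s, d) {
  if (any(d <= 0)) stop("slater_potential: d must be > 0 (self-interaction ",
                        "is not defined here)", call. = FALSE)
  if (s <= 0) stop("slater_potential: width must be > 0", call. = FALSE)
  q / d + (n_val / d) * exp(-d / s) * (1 + d / (2 * s))
}

# dV/dd for the Slater-atom potential (atomic units).
.slater_dVdd <- function(q, n_val, s, d) {
  -q / d^2 - n_val * exp(-d / s) * ((1 / s) * (1 / d + 1 / (2 * s)) + 1 / d^2)
}

#' Electronegativity-equalization atomic charges
#'
#' Minimizes `sum_i (chi_i q_i + eta_i q_i^2 / 2) + sum_{i<j} q_i q_j / d_ij`
#' subject to `sum q_i = Q`, solved as an (N+1)-dimensional symmetric linear
#' system with a Lagrange multiplier. All quantities in atomic units.
#'
#' With `smear` widths, the off-diagonal Coulomb kernel is Gaussian-smeared,
#' `erf(d / sqrt(2 (s_i^2 + s_j^2))) / d`, which stays finite as atoms
#' approach and prevents the polarization catastrophe of the bare `1/d`
#' kernel at close contact; the bare kernel is the default.
#'
#' @param chi per-atom electronegativities (hartree / e).
#' @param eta per-atom hardnesses (hartree / e^2).
#' @param coords_bohr n x 3 coordinates (bohr).
#' @param total_charge total charge (e).
#' @param smear optional per-atom smearing widths (bohr) for the
#'   off-diagonal kernel.
#' @return list with `charges` and the Lagrange multiplier `lambda`.
#' @export
eeq_charges <- function(chi, eta, coords_bohr, total_charge, smear = NULL) {
  n <- length(chi)
  if (n == 1L) return(list(charges = total_charge, lambda = NA_real_))
  dmat <- as.matrix(stats::dist(coords_bohr))
  h <- .eeq_kernel(dmat, smear)
  diag(h) <- eta
  if (!all(is.finite(h))) {
    stop("singular equalization matrix: coincident atoms", call. = FALSE)
  }
  a <- rbind(cbind(h, 1), c(rep(1, n), 0))
  rhs <- c(-chi, total_charge)
  sol <- tryCatch(solve(a, rhs), error = function(e) {
    stop("singular equalization matrix: ", conditionMessage(e), call. = FALSE)
  })
  list(charges = unname(sol[seq_len(n)]), lambda = unname(sol[n + 1L]))
}

# Off-diagonal equalization kernel: bare 1/d, or Gaussian-smeared when
# per-atom widths are given.
.eeq_kernel <- function(dmat, smear = NULL) {
  if (is.null(smear)) return(1 / dmat)
  gam <- sqrt(2 * outer(smear^2, smear^2, "+"))
  k <- erf_(dmat / gam) / dmat
  diag(k) <- 0
  k
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# Inverse of eeq_charges (gauge lambda = 0): electronegativity targets that
# make equalization reproduce the reference charges for this geometry.
.eeq_chi_targets <- function(charges, eta, coords_bohr, smear = NULL) {
  n <- length(charges)
  if (n == 1L) return(-eta * charges)
  dmat <- as.matrix(stats::dist(coords_bohr))
  inv <- .eeq_kernel(dmat, smear)
  diag(inv) <- 0
  -(eta * charges + as.numeric(inv %*% charges))
}

#' Bundle the trained static-electrostatics model
#'
#' @param electronegativity_model,width_model,volume_model
#'   [fit_per_element_gpr()] models predicting per-atom electronegativity
#'   (hartree/e), Slater width (bohr) and volume (bohr^3) from descriptors.
#' @param settings the shared [descriptor_settings()].
#' @param hardness_rule documented map width -> hardness; only
#'   `"half_inverse_width"` (`eta = 1 / (2 s)`) is built in.
#' @return an object of class `static_model`.
#' @export
static_model <- function(electronegativity_model, width_model, volume_model,
                         settings, hardness_rule = "half_inverse_width") {
  stopifnot(inherits(settings, "descriptor_settings"))
  if (!identical(hardness_rule, "half_inverse_width")) {
    stop("unknown hardness_rule: ", hardness_rule, call. = FALSE)
  }
  structure(list(electronegativity_model = electronegativity_model,
                 width_model = width_model,
                 volume_model = volume_model,
                 settings = settings,
                 hardness_rule = hardness_rule),
            class = "static_model")
}

.hardness_from_width <- function(model, widths) 1 / (2 * widths)

#' Predict conformation-dependent density parameters
#'
#' Widths and volumes come directly from their GPR models (with a
#' softplus-style positivity floor); charges from electronegativity
#' equalization with hardness `eta = 1/(2 s)` and the Gaussian-smeared
#' off-diagonal kernel (smearing width = predicted Slater width), so the
#' predicted charges are conformation-dependent, conserve the region's
#' total charge exactly, and stay bounded at close contact.
#'
#' @param model a [static_model()] (or ground-truth backend implementing the
#'   same contract).
#' @param region an [ml_region()].
#' @return a [density_parameters()] object.
#' @export
predict_density <- function(model, region) UseMethod("predict_density")

#' @export
predict_density.static_model <- function(model, region) {
  feat <- compute_descriptors(region, model$settings)
  el <- region$elements
  widths <- .softplus_floor(predict(model$width_model, feat, el), 0.05)
  volumes <- .softplus_floor(predict(model$volume_model, feat, el), 0.1)
  chi <- predict(model$electronegativity_model, feat, el)
  eta <- .hardness_from_width(model, widths)
  coords_bohr <- region$coordinates / BOHR_TO_ANGSTROM
  q <- eeq_charges(chi, eta, coords_bohr, region$total_charge,
                   smear = widths)$charges
  density_parameters(q, widths, .valence_for(el), volumes,
                     total_charge = region$total_charge)
}

#' Train a static-electrostatics model from reference density tables
#'
#' Reference per-atom charges are converted to electronegativity targets by
#' inverting the equalization conditions at each reference geometry (gauge:
#' zero Lagrange multiplier), so that equalization with the learned
#' electronegativities reproduces the reference charges.
#'
#' @param frames list of [ml_region()] conformers.
#' @param properties data.frame with columns `frame_id`, `atom_index`,
#'   `element`, `q`, `s`, `v` (atomic units), as written by
#'   [emit_reference_tables()].
#' @param settings a [descriptor_settings()].
#' @param n_inducing,lengthscale,variance,noise_variance,seed GPR
#'   hyperparameters, see [fit_sparse_gpr()].
#' @return a [static_model()].
#' @export
fit_static_model <- function(frames, properties, settings,
                             n_inducing = 48L, lengthscale = 1.0,
                             variance = NULL, noise_variance = 1e-8,
                             seed = 1L) {
  dat <- .stack_property_rows(frames, properties, settings)
  eta <- 1 / (2 * dat$s)
  chi <- numeric(nrow(dat$features))
  for (fid in unique(dat$frame_id)) {
    sel <- dat$frame_id == fid
    coords_bohr <- frames[[fid]]$coordinates / BOHR_TO_ANGSTROM
    chi[sel] <- .eeq_chi_targets(dat$q[sel], eta[sel], coords_bohr,
                                 smear = dat$s[sel])
  }
  fit1 <- function(y) {
    v <- if (is.null(variance)) max(stats::var(y), 1e-8) else variance
    fit_per_element_gpr(dat$features, y, dat$elements,
                        n_inducing = n_inducing, lengthscale = lengthscale,
                        variance = v, noise_variance = noise_variance,
                        seed = seed)
  }
  static_model(fit1(chi), fit1(dat$s), fit1(dat$v), settings)
}

# Stack per-frame descriptors and reference properties into flat arrays.
.stack_property_rows <- function(frames, properties, settings) {
  feats <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    feats[[i]] <- compute_descriptors(frames[[i]], settings)
  }
  ord <- order(properties$frame_id, properties$atom_index)
  properties <- properties[ord, ]
  features <- do.call(rbind, feats)
  expected <- sum(vapply(frames, n_atoms, integer(1)))
  if (nrow(properties) != expected) {
    stop("property table rows do not match frames", call. = FALSE)
  }
  list(features = features,
       frame_id = properties$frame_id,
       elements = as.character(properties$element),
       q = properties$q, s = properties$s, v = properties$v)
}

# Shared distance setup for ML <-> MM pair interactions (bohr).
.pair_geometry <- function(region, env, min_dist = 0.1) {
  rml <- region$coordinates / BOHR_TO_ANGSTROM
  rmm <- env$positions / BOHR_TO_ANGSTROM
  dx <- outer(rml[, 1], rmm[, 1], "-")
  dy <- outer(rml[, 2], rmm[, 2], "-")
  dz <- outer(rml[, 3], rmm[, 3], "-")
  d <- sqrt(dx^2 + dy^2 + dz^2)
  if (any(d < min_dist)) {
    stop("overlapping ML/MM atoms (distance < ", min_dist, " bohr)",
         call. = FALSE)
  }
  list(dx = dx, dy = dy, dz = dz, d = d)
}

#' Static ML-MM interaction energy with charge penetration
#'
#' `E_static = sum_{j in MM} q_j * sum_{i in ML} V_i(|r_j - R_i|)` with the
#' Slater-atom potential of [slater_potential()]. Density parameters are
#' held fixed for the analytic gradients (the fast force path); geometry
#' response of the parameters is available through the finite-difference
#' force mode of [total_energy()].
#'
#' @param density a [density_parameters()].
#' @param region an [ml_region()].
#' @param env an [mm_environment()].
#' @param gradient if `TRUE`, return analytic forces on ML and MM atoms.
#' @return energy in hartree; with `gradient = TRUE` a list
#'   `(energy, forces_ml, forces_mm)` with forces in hartree/bohr.
#' @export
static_energy <- function(density, region, env, gradient = FALSE) {
  if (length(density$charges) != n_atoms(region)) {
    stop("density parameters do not match region size", call. = FALSE)
  }
  g <- .pair_geometry(region, env)
  nml <- n_atoms(region)
  v <- matrix(0, nml, nrow(env$positions))
  for (i in seq_len(nml)) {
    v[i, ] <- slater_potential(density$charges[i],
                               density$valence_populations[i],
                               density$widths[i], g$d[i, ])
  }
  energy <- sum(colSums(v) * env$charges)
  if (!gradient) return(energy)
  fml <- matrix(0, nml, 3)
  fmm <- matrix(0, nrow(env$positions), 3)
  for (i in seq_len(nml)) {
    dvdd <- .slater_dVdd(density$charges[i], density$valence_populations[i],
                         density$widths[i], g$d[i, ])
    coef <- env$charges * dvdd / g$d[i, ]
    gx <- coef * g$dx[i, ]; gy <- coef * g$dy[i, ]; gz <- coef * g$dz[i, ]
    fml[i, ] <- -c(sum(gx), sum(gy), sum(gz))
    fmm[, 1] <- fmm[, 1] + gx
    fmm[, 2] <- fmm[, 2] + gy
    fmm[, 3] <- fmm[, 3] + gz
  }
  list(energy = energy, forces_ml = fml, forces_mm = fmm)
}

#' Fixed-charge Coulomb coupling (MM embedding)
#'
#' Plain Coulomb interaction between fixed ML point charges and MM point
#' charges: no charge penetration, no conformational charge response. Used
#' by the `mm_fixed` embedding ablation with named charge sets (e.g.
#' reactant-derived `q_R`, product-derived `q_P`).
#'
#' @param fixed_charges per-ML-atom charges (e).
#' @param region an [ml_region()].
#' @param env an [mm_environment()].
#' @param gradient if `TRUE`, return analytic forces.
#' @return energy in hartree; with `gradient = TRUE` a list
#'   `(energy, forces_ml, forces_mm)` in atomic units.
#' @export
mm_embedding_energy <- function(fixed_charges, region, env, gradient = FALSE) {
  if (length(fixed_charges) != n_atoms(region)) {
    stop("fixed_charges length must equal ML atom count", call. = FALSE)
  }
  g <- .pair_geometry(region, env)
  inv <- 1 / g$d
  energy <- as.numeric(fixed_charges %*% inv %*% env$charges)
  if (!gradient) return(energy)
  coef <- outer(fixed_charges, env$charges) * inv^3
  fml <- cbind(rowSums(coef * g$dx), rowSums(coef * g$dy),
               rowSums(coef * g$dz))
  list(energy = energy, forces_ml = fml,
       forces_mm = -cbind(colSums(coef * g$dx), colSums(coef * g$dy),
                          colSums(coef * g$dz)))
}
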