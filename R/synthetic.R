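#' Ground-truth generator emulating gas-phase QM reference data
#'
#' Defines an exactly known "electronic structure" for the toy reactive
#' molecule: per-atom charges, Slater valence widths and volumes that vary
#' smoothly with the reaction coordinate through a documented sigmoid, a
#' true per-element polarizability/volume map `k_Z`, and a true
#' environment-dependent correction field `k_alpha` that peaks in the
#' transition-state region (the reactive pair roughly doubles its
#' polarizability there, mimicking an oxyanion-like species). Together with
#' the analytic gas-phase surface this supplies everything a set of
#' gas-phase QM reference calculations would: per-atom properties,
#' molecular polarizability tensors, and embedded reference energies.
#'
#' The charge rearrangement along the reaction is deliberately large
#' (0.6 e transferred onto the leaving oxygen) so that fixed-charge
#' embedding fails visibly and the embedding ablations have a strict
#' expected ordering.
#'
#' @param surface a [toy_reactive_surface()]; built with defaults if
#'   omitted.
#' @param k_z true per-element polarizability/volume ratios.
#' @param charge_transfer electrons transferred onto O1 across the
#'   reaction (e).
#' @param sigmoid_width width of the property sigmoid in the RC (angstrom).
#' @param k_alpha_amp amplitude of the true `k_alpha` bump on the reactive
#'   pair (1 = doubling at the peak).
#' @param k_alpha_center,k_alpha_width location/width of the bump in the RC.
#' @param thole_damping_a Thole damping constant of the ground truth.
#' @return an object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(surface = NULL,
                               k_z = c(H = 0.45, C = 0.60, O = 0.45),
                               charge_transfer = 0.6,
                               sigmoid_width = 0.25,
                               k_alpha_amp = 1.0,
                               k_alpha_center = -0.1,
                               k_alpha_width = 0.3,
                               thole_damping_a = 0.39) {
  if (is.null(surface)) surface <- toy_reactive_surface()
  gt <- structure(list(
    surface = surface,
    k_z = k_z,
    charge_transfer = charge_transfer,
    sigmoid_width = sigmoid_width,
    k_alpha_amp = k_alpha_amp,
    k_alpha_center = k_alpha_center,
    k_alpha_width = k_alpha_width,
    thole_damping_a = thole_damping_a,
    # reactant-side base properties (sum of charges = -1)
    q_base = c(O1 = -0.40, C2 = 0.15, C3 = -0.60, H4 = -0.05, H5 = -0.10),
    s_base = c(O1 = 0.42, C2 = 0.60, C3 = 0.62, H4 = 0.31, H5 = 0.31),
    v_base = c(O1 = 22, C2 = 34, C3 = 36, H4 = 7, H5 = 7),
    s_amp = c(O1 = 0.10, C2 = -0.05, C3 = -0.04, H4 = 0.01, H5 = 0.01),
    v_amp = c(O1 = 8, C2 = -4, C3 = 2, H4 = 0.5, H5 = 0.5),
    ml_lj = list(sigma = c(3.0, 3.4, 3.4, 2.5, 2.5),
                 epsilon = c(0.17, 0.09, 0.09, 0.02, 0.02)),
    total_charge = -1L
  ), class = "ground_truth_model")
  gt
}

#' @export
print.ground_truth_model <- function(x, ...) {
  cat("ground_truth_model over the toy reactive molecule (",
      x$charge_transfer, "e transfer, k_alpha peak ",
      1 + x$k_alpha_amp, "x at RC ", x$k_alpha_center, " A)\n", sep = "")
  invisible(x)
}

# Sigmoid of the reaction progress used by all property rules.
.gt_sigmoid <- function(gt, xi) 1 / (1 + exp(-xi / gt$sigmoid_width))

#' Exact per-atom properties of the ground truth at a geometry
#'
#' @param gt a [ground_truth_model()].
#' @param region an [ml_region()] of the toy molecule.
#' @return list with `q`, `s` (bohr), `v` (bohr^3), `k_alpha`, `alphas`
#'   (bohr^3), `xi` (angstrom).
#' @export
gt_properties <- function(gt, region) {
  xi <- evaluate_rc(toy_rc(), region)
  g <- .gt_sigmoid(gt, xi)
  q <- gt$q_base + g * gt$charge_transfer * c(-1, 0.5, 0.5, 0, 0)
  s <- gt$s_base + g * gt$s_amp
  v <- gt$v_base + g * gt$v_amp
  ka <- rep(1, 5)
  bump <- exp(-(xi - gt$k_alpha_center)^2 / (2 * gt$k_alpha_width^2))
  ka[1:2] <- 1 + gt$k_alpha_amp * bump
  alphas <- unname(gt$k_z[region$elements]) * v * ka
  list(q = unname(q), s = unname(s), v = unname(v), k_alpha = ka,
       alphas = unname(alphas), xi = xi)
}

#' @export
predict_density.ground_truth_model <- function(model, region) {
  p <- gt_properties(model, region)
  density_parameters(p$q, p$s, .valence_for(region$elements), p$v,
                     total_charge = model$total_charge)
}

#' Ground-truth polarizability backend
#'
#' Wraps a [ground_truth_model()] so it can stand in for a trained
#' [polarizability_model()] (e.g. in [total_energy()]).
#'
#' @param gt a [ground_truth_model()].
#' @param mode `"flexible"` (true `k_alpha` field) or `"fixed"`
#'   (`k_alpha = 1`).
#' @return an object usable wherever a polarizability model is accepted.
#' @export
gt_polarizability_backend <- function(gt, mode = c("flexible", "fixed")) {
  mode <- match.arg(mode)
  structure(list(gt = gt, mode = mode,
                 thole_damping_a = gt$thole_damping_a),
            class = "gt_pol_backend")
}

#' @export
atomic_polarizabilities.gt_pol_backend <- function(model, density, region) {
  p <- gt_properties(model$gt, region)
  if (model$mode == "fixed") {
    unname(model$gt$k_z[region$elements]) * p$v
  } else {
    p$alphas
  }
}

#' Fixed charge sets from the ground truth (reactant/product-derived)
#'
#' @param gt a [ground_truth_model()].
#' @param state `"reactant"` (q_R) or `"product"` (q_P).
#' @return per-atom charge vector.
#' @export
gt_fixed_charges <- function(gt, state = c("reactant", "product")) {
  state <- match.arg(state)
  region <- toy_equilibrium_region(gt$surface, state,
                                   total_charge = gt$total_charge)
  gt_properties(gt, region)$q
}

#' Generate conformers stratified across the reaction coordinate
#'
#' Frames are placed on an even RC grid spanning the reactant-to-product
#' range of the toy surface (so coverage has no large gaps), built from the
#' ideal geometry at each RC value plus a small Gaussian coordinate jitter.
#' Deterministic given the seed.
#'
#' @param gt a [ground_truth_model()].
#' @param n number of conformers.
#' @param seed integer seed.
#' @param jitter coordinate jitter standard deviation (angstrom).
#' @param rc_range RC interval to span; defaults to slightly beyond the two
#'   minima of the surface.
#' @return list of [ml_region()] frames; RC values in attribute `rc`.
#' @export
generate_conformers <- function(gt, n, seed = 1L, jitter = 0.02,
                                rc_range = NULL) {
  p <- gt$surface$params
  if (is.null(rc_range)) {
    rc_range <- c(p$rc_reactant - 0.15, p$rc_product + 0.15)
  }
  set.seed(as.integer(seed))
  xis <- seq(rc_range[1], rc_range[2], length.out = n) +
    stats::runif(n, -0.2, 0.2) * diff(rc_range) / n
  rc <- toy_rc()
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    co <- .toy_geometry(p, xis[i]) + matrix(stats::rnorm(15, 0, jitter), 5, 3)
    reg <- ml_region(.toy_elements, co, gt$total_charge, .toy_labels)
    # put the jittered frame back on its stratification target: shift C2
    # along the RC gradient so the RC is exact (keeps coverage guarantees)
    for (newton in 1:3) {
      ev <- evaluate_rc(rc, reg, gradient = TRUE)
      miss <- xis[i] - ev$value
      if (abs(miss) < 1e-9) break
      g2 <- sum(ev$gradient[2, ]^2)
      reg$coordinates[2, ] <- reg$coordinates[2, ] +
        miss * ev$gradient[2, ] / g2
    }
    frames[[i]] <- reg
  }
  attr(frames, "rc") <- vapply(frames, function(r)
    evaluate_rc(toy_rc(), r), numeric(1))
  frames
}

#' Assemble a training set from seeds, window subsamples and extras
#'
#' Concatenates seed structures, `per_window` subsamples from each window
#' pool (evenly spaced through each pool, deterministic), and additional
#' per-window extras; rejects duplicate frames and records a manifest of
#' counts and provenance.
#'
#' @param seed_structures list of structures.
#' @param windows list of per-window structure pools.
#' @param per_window how many structures to take from every window pool.
#' @param extra optional named map (window index as name) -> extra count
#'   taken from that pool beyond `per_window`.
#' @return list with `structures` and `manifest` (data.frame of source and
#'   count; total in attribute `total`).
#' @export
assemble_training_set <- function(seed_structures, windows = list(),
                                  per_window = 0L, extra = NULL) {
  main_idx <- function(len, k) {
    if (k > len) {
      stop("window pool has only ", len, " structures; need ", k,
           call. = FALSE)
    }
    idx <- unique(round(seq(1, len, length.out = k)))
    if (length(idx) < k) idx <- seq_len(k)
    idx
  }
  structures <- as.list(seed_structures)
  manifest <- data.frame(source = "seed", count = length(seed_structures))
  taken <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    taken[[w]] <- if (per_window > 0) {
      main_idx(length(windows[[w]]), per_window)
    } else integer(0)
    structures <- c(structures, windows[[w]][taken[[w]]])
    manifest <- rbind(manifest,
                      data.frame(source = sprintf("window_%d", w),
                                 count = length(taken[[w]])))
  }
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      w <- as.integer(nm)
      avail <- setdiff(seq_along(windows[[w]]), taken[[w]])
      k <- extra[[nm]]
      if (k > length(avail)) {
        stop("window pool ", w, " has only ", length(avail),
             " unused structures; need ", k, call. = FALSE)
      }
      sel <- avail[seq_len(k)]
      structures <- c(structures, windows[[w]][sel])
      manifest <- rbind(manifest,
                        data.frame(source = sprintf("window_%d_extra", w),
                                   count = k))
    }
  }
  keys <- vapply(structures, function(s) {
    paste(format(unlist(s, use.names = FALSE), digits = 15), collapse = ",")
  }, character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate frames in assembled training set", call. = FALSE)
  }
  out <- list(structures = structures, manifest = manifest)
  attr(out, "total") <- length(structures)
  out
}

#' Generate a random point-charge environment around the ML region
#'
#' Point charges are placed uniformly in a sphere (`"droplet"`) or on a
#' spherical shell (`"shell"`) around the region centroid, rejecting
#' positions closer than `min_approach` to any ML atom. Charges are drawn
#' uniformly and optionally shifted to exact net neutrality. Deterministic
#' given the seed.
#'
#' @param region the [ml_region()] to surround.
#' @param style `"droplet"` or `"shell"`.
#' @param n_charges number of point charges.
#' @param radius sphere radius (angstrom).
#' @param charge_scale charges drawn from `U(-scale, scale)`.
#' @param min_approach minimum distance to any ML atom (angstrom).
#' @param net_neutral shift charges to sum exactly to zero.
#' @param lj if `TRUE`, assign water-oxygen-like Lennard-Jones parameters
#'   (sigma 3.15 A, epsilon 0.152 kcal/mol) to every charge.
#' @param seed integer seed.
#' @return an [mm_environment()].
#' @export
generate_environment <- function(region, style = c("droplet", "shell"),
                                 n_charges = 32L, radius = 8,
                                 charge_scale = 0.4, min_approach = 3,
                                 net_neutral = TRUE, lj = FALSE, seed = 1L) {
  style <- match.arg(style)
  set.seed(as.integer(seed))
  centroid <- colMeans(region$coordinates)
  pos <- matrix(0, n_charges, 3)
  placed <- 0L
  tries <- 0L
  while (placed < n_charges) {
    tries <- tries + 1L
    if (tries > 10000L * n_charges) {
      stop("could not place charges outside min_approach; enlarge radius",
           call. = FALSE)
    }
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- if (style == "shell") radius else radius * stats::runif(1)^(1 / 3)
    cand <- centroid + r * u
    dmin <- min(sqrt(rowSums(sweep(region$coordinates, 2, cand)^2)))
    if (dmin >= min_approach) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
  }
  q <- stats::runif(n_charges, -charge_scale, charge_scale)
  if (net_neutral) q <- q - mean(q)
  mm_environment(pos, q,
                 lj_sigma = if (lj) rep(3.15, n_charges),
                 lj_epsilon = if (lj) rep(0.152, n_charges))
}

#' Enzyme-like point-charge environment for the toy reaction
#'
#' A neutral random droplet plus one "catalytic" positive charge placed
#' close to the leaving oxygen, mimicking an active-site residue that
#' stabilizes the developing oxyanion. Because 0.6 e moves onto O1 across
#' the reaction and the reactive pair's polarizability peaks at the
#' transition state, this environment makes the static and induced
#' components both strongly reaction-dependent — the regime in which
#' fixed-charge MM embedding fails and the induction term matters.
#'
#' @param gt a [ground_truth_model()].
#' @param n_bath number of neutral-bath charges.
#' @param catalytic_charge magnitude of the active-site charge (e).
#' @param catalytic_distance distance from the O1 end (angstrom).
#' @param seed integer seed for the bath.
#' @return an [mm_environment()].
#' @export
gt_catalytic_environment <- function(gt, n_bath = 20L, catalytic_charge = 0.7,
                                     catalytic_distance = 3.0, seed = 1L) {
  reg <- toy_equilibrium_region(gt$surface, "reactant",
                                total_charge = gt$total_charge)
  bath <- generate_environment(reg, "droplet", n_charges = n_bath,
                               radius = 7.5, charge_scale = 0.3,
                               min_approach = 3.2, net_neutral = TRUE,
                               lj = TRUE, seed = seed)
  # O1 sits near the origin with the molecule along +x: put the catalytic
  # charge on the far side of O1
  pos <- rbind(bath$positions,
               reg$coordinates[1, ] + c(-catalytic_distance, 0.5, 0))
  mm_environment(pos, c(bath$charges, catalytic_charge),
                 lj_sigma = c(bath$lj_sigma, 3.15),
                 lj_epsilon = c(bath$lj_epsilon, 0.152))
}

#' Binding-pocket anchors for the toy substrate
#'
#' Isotropic harmonic position restraints on the two frame atoms (O1 and
#' C3) at their reactant-state positions, holding the substrate in the
#' model active site during sampling (the stand-in for the enzyme's
#' binding interactions). Identical across embedding variants, so PMF
#' differences between variants are unaffected in expectation.
#'
#' @param gt a [ground_truth_model()].
#' @param force_constant anchor force constant (kcal/mol/A^2).
#' @return list of two [restraint()] objects.
#' @export
gt_pocket_restraints <- function(gt, force_constant = 20) {
  reg <- toy_equilibrium_region(gt$surface, "reactant",
                                total_charge = gt$total_charge)
  list(restraint("position", pair = "O1", target = reg$coordinates[1, ],
                 force_constant = force_constant),
       restraint("position", pair = "C3", target = reg$coordinates[3, ],
                 force_constant = force_constant))
}

#' Emit reference tables from the ground truth
#'
#' Produces the tables a set of reference QM calculations would provide:
#' per-atom properties (`frame_id, atom_index, element, q, s, v`, atomic
#' units), molecular polarizability tensors (`frame_id, xx, xy, xz, yy,
#' yz, zz`, atomic units), and embedded reference energies
#' (`frame_id, e_gas_ref, e_static_ref, e_induced_ref, e_mm_ref,
#' e_total_ref`, kcal/mol) evaluated exactly from the ground-truth density
#' and Thole model.
#'
#' @param gt a [ground_truth_model()].
#' @param frames list of [ml_region()] conformers.
#' @param environments one [mm_environment()] or a list (one per frame);
#'   `NULL` skips the energy table.
#' @param polarizability_mode `"flexible"` (true `k_alpha` field) or
#'   `"fixed"`.
#' @param dir optional directory; when given, the tables are also written
#'   as `properties.csv`, `polarizabilities.csv`, `energies.csv`.
#' @return list of data.frames `properties`, `polarizabilities`, and (with
#'   environments) `energies`.
#' @export
emit_reference_tables <- function(gt, frames, environments = NULL,
                                  polarizability_mode = "flexible",
                                  dir = NULL) {
  props <- list()
  pols <- list()
  energies <- list()
  pol_backend <- gt_polarizability_backend(gt, polarizability_mode)
  if (!is.null(environments) && inherits(environments, "mm_environment")) {
    environments <- rep(list(environments), length(frames))
  }
  for (i in seq_along(frames)) {
    region <- frames[[i]]
    p <- gt_properties(gt, region)
    props[[i]] <- data.frame(frame_id = i, atom_index = seq_len(5),
                             element = region$elements,
                             q = p$q, s = p$s, v = p$v)
    alphas <- atomic_polarizabilities(pol_backend, NULL, region)
    ten <- molecular_polarizability(alphas, region,
                                    gt$thole_damping_a)$tensor
    pols[[i]] <- data.frame(frame_id = i,
                            xx = ten[1, 1], xy = ten[1, 2], xz = ten[1, 3],
                            yy = ten[2, 2], yz = ten[2, 3], zz = ten[3, 3])
    if (!is.null(environments)) {
      dec <- total_energy(region, environments[[i]], gt$surface,
                          static = gt, pol = pol_backend,
                          variant = embedding_variant("emle"),
                          ml_lj = gt$ml_lj)
      energies[[i]] <- data.frame(frame_id = i,
                                  e_gas_ref = dec$e_gas,
                                  e_static_ref = dec$e_static,
                                  e_induced_ref = dec$e_induced,
                                  e_mm_ref = dec$e_mm,
                                  e_total_ref = dec$e_total)
    }
  }
  out <- list(properties = do.call(rbind, props),
              polarizabilities = do.call(rbind, pols))
  if (!is.null(environments)) out$energies <- do.call(rbind, energies)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(out$properties, file.path(dir, "properties.csv"),
                     row.names = FALSE)
    utils::write.csv(out$polarizabilities,
                     file.path(dir, "polarizabilities.csv"),
                     row.names = FALSE)
    if (!is.null(out$energies)) {
      utils::write.csv(out$energies, file.path(dir, "energies.csv"),
                       row.names = FALSE)
    }
  }
  out
}
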