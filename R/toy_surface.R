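#' Analytic reactive gas-phase surface over a five-atom toy molecule
#'
#' A documented stand-in for a trained gas-phase reactive MLP: a model
#' atom-transfer system `O1-C2 ... C3` (with one spectator hydrogen on each
#' carbon) in which the O1-C2 bond breaks while the C2-C3 bond forms. The
#' reaction coordinate is the distance difference
#' `xi = d(O1-C2) - d(C2-C3)`. Two Morse-bonded diabatic states (reactant:
#' O-C bonded; product: C-C bonded) are coupled through a smooth logistic
#' switching function of `xi`, plus a Gaussian barrier-control term and
#' harmonic frame/spectator bonds. The constructor calibrates the barrier
#' height and reaction asymmetry of the relaxed 1D profile to the requested
#' values (deterministic 1D scans with constrained minimization).
#'
#' @param barrier requested barrier height of the relaxed profile
#'   (kcal/mol, relative to the reactant minimum).
#' @param asymmetry requested reaction energy (product minimum minus
#'   reactant minimum, kcal/mol); 0 gives a profile symmetric in energy.
#' @param params optional overrides of the surface parameters (see
#'   `toy_surface_params()` defaults).
#' @return a [gas_phase_potential()] with the calibrated parameter list in
#'   `$params` (including the located `rc_reactant`, `rc_product`).
#' @export
toy_reactive_surface <- function(barrier = 20, asymmetry = -3,
                                 params = list()) {
  p <- utils::modifyList(toy_surface_params(), params)
  p$delta <- asymmetry
  p$bump <- 0
  p$bump_center <- 0
  for (iter in 1:12) {
    pot <- .toy_energy_closure(p)
    prof <- .toy_profile(pot, p)
    err_b <- barrier - prof$barrier
    err_a <- asymmetry - prof$asymmetry
    p$bump <- p$bump + err_b
    p$delta <- p$delta + err_a
    p$bump_center <- prof$rc_ts
    if (abs(err_b) < 1e-4 && abs(err_a) < 1e-4) break
  }
  pot <- .toy_energy_closure(p)
  prof <- .toy_profile(pot, p)
  p$rc_reactant <- prof$rc_reactant
  p$rc_product <- prof$rc_product
  p$barrier <- prof$barrier
  p$asymmetry <- prof$asymmetry
  out <- gas_phase_potential(pot, "toy_reactive_surface",
                             elements = c("O", "C", "H"),
                             probe = list(toy_equilibrium_region(p, "reactant"),
                                          toy_equilibrium_region(p, "ts")),
                             validate = TRUE,
                             notes = "model O-C cleavage / C-C formation")
  out$params <- p
  out
}

#' Default parameters of the toy reactive surface
#'
#' Distances in angstrom, energies kcal/mol. `morse_d` and `morse_a` set
#' both diabatic Morse wells; `frame_l`/`frame_k` hold the O1...C3 frame;
#' `rep_a`/`rep_rho` is the non-bonded exponential repulsion of the
#' spectating distance in each diabat; `switch_width` the logistic coupling
#' width in `xi`.
#' @return named parameter list.
#' @export
toy_surface_params <- function() {
  list(morse_d = 90, morse_a = 2.0, r_oc = 1.35, r_cc = 1.52,
       frame_l = 3.6, frame_k = 100, col_k = 50, r_ch = 1.09, ch_k = 300,
       rep_a = 100, rep_rho = 0.4, switch_width = 0.15,
       nb_rep_a = 80, nb_rep_rho = 0.25,
       bump_sigma = 0.3, bump = 0, bump_center = 0, delta = 0)
}

# The toy RC as a reaction_coordinate over the standard labels.
#' Reaction coordinate of the toy system: d(O1-C2) - d(C2-C3)
#' @return a [reaction_coordinate()].
#' @export
toy_rc <- function() {
  reaction_coordinate("distance_difference",
                      list(c("O1", "C2"), c("C2", "C3")), c(1, -1))
}

# Collinear starting geometry of the toy molecule at a given xi.
.toy_geometry <- function(p, xi) {
  x_c2 <- (p$frame_l + xi) / 2
  rbind(c(0, 0, 0),
        c(x_c2, 0, 0),
        c(p$frame_l, 0, 0),
        c(x_c2, p$r_ch, 0),
        c(p$frame_l, -p$r_ch, 0))
}

.toy_elements <- c("O", "C", "C", "H", "H")
.toy_labels <- c("O1", "C2", "C3", "H4", "H5")

#' Relaxed toy-molecule geometry at a reaction-coordinate value
#'
#' @param surface a [toy_reactive_surface()] (or its `$params` list).
#' @param state `"reactant"`, `"product"`, `"ts"`, or a numeric xi value
#'   (angstrom).
#' @param total_charge total charge carried by the region (the embedding
#'   ground truth uses -1 by default; the gas surface itself is
#'   charge-agnostic).
#' @return an [ml_region()] minimized at the requested xi.
#' @export
toy_equilibrium_region <- function(surface, state = "reactant",
                                   total_charge = -1L) {
  p <- if (inherits(surface, "gas_phase_potential")) surface$params else surface
  pot <- .toy_energy_closure(p)
  xi <- if (is.numeric(state)) state else switch(
    state,
    reactant = p$rc_reactant %||% -0.85,
    product = p$rc_product %||% 0.55,
    ts = p$bump_center,
    stop("unknown state: ", state, call. = FALSE))
  coords <- .toy_relax(pot, p, xi)
  ml_region(.toy_elements, coords, total_charge, .toy_labels)
}

# Energy closure over the parameter list: function(region) -> E, gradient.
.toy_energy_closure <- function(p) {
  force(p)
  function(region) {
    co <- region$coordinates
    pr <- function(i, j) {
      dv <- co[i, ] - co[j, ]
      d <- sqrt(sum(dv^2))
      list(d = d, u = dv / d)
    }
    oc <- pr(1, 2); cc <- pr(2, 3); fr <- pr(1, 3)
    ch1 <- pr(2, 4); ch2 <- pr(3, 5)
    xi <- oc$d - cc$d
    morse <- function(d, r0) {
      e <- exp(-p$morse_a * (d - r0))
      list(v = p$morse_d * (1 - e)^2, g = 2 * p$morse_d * p$morse_a * (1 - e) * e)
    }
    rep_ <- function(d) {
      v <- p$rep_a * exp(-d / p$rep_rho)
      list(v = v, g = -v / p$rep_rho)
    }
    m1 <- morse(oc$d, p$r_oc); m2 <- morse(cc$d, p$r_cc)
    rp_cc <- rep_(cc$d); rp_oc <- rep_(oc$d)
    s <- 1 / (1 + exp(-xi / p$switch_width))
    ds <- s * (1 - s) / p$switch_width
    gb <- exp(-(xi - p$bump_center)^2 / (2 * p$bump_sigma^2))
    bump <- p$bump * gb
    dbump <- -p$bump * gb * (xi - p$bump_center) / p$bump_sigma^2
    e_r <- m1$v + rp_cc$v
    e_p <- m2$v + rp_oc$v + p$delta
    # collinearity penalty localizes both wells along the frame axis
    col_dev <- oc$d + cc$d - fr$d
    # short-range exchange-like repulsion between the nonbonded pairs not
    # covered above, so spectator atoms cannot collapse onto the core
    nb_pairs <- list(pr(1, 4), pr(1, 5), pr(2, 5), pr(3, 4), pr(4, 5))
    nb_e <- vapply(nb_pairs, function(pp) {
      p$nb_rep_a * exp(-pp$d / p$nb_rep_rho)
    }, numeric(1))
    energy <- (1 - s) * e_r + s * e_p + bump + sum(nb_e) +
      0.5 * p$frame_k * (fr$d - p$frame_l)^2 +
      0.5 * p$col_k * col_dev^2 +
      0.5 * p$ch_k * (ch1$d - p$r_ch)^2 +
      0.5 * p$ch_k * (ch2$d - p$r_ch)^2
    dcol <- p$col_k * col_dev
    de_dxi <- ds * (e_p - e_r) + dbump
    de_doc <- (1 - s) * m1$g + s * rp_oc$g + de_dxi + dcol
    de_dcc <- (1 - s) * rp_cc$g + s * m2$g - de_dxi + dcol
    grad <- matrix(0, 5, 3)
    add <- function(grad, i, j, dedd, u) {
      grad[i, ] <- grad[i, ] + dedd * u
      grad[j, ] <- grad[j, ] - dedd * u
      grad
    }
    grad <- add(grad, 1, 2, de_doc, oc$u)
    grad <- add(grad, 2, 3, de_dcc, cc$u)
    grad <- add(grad, 1, 3, p$frame_k * (fr$d - p$frame_l) - dcol, fr$u)
    grad <- add(grad, 2, 4, p$ch_k * (ch1$d - p$r_ch), ch1$u)
    grad <- add(grad, 3, 5, p$ch_k * (ch2$d - p$r_ch), ch2$u)
    nb_idx <- list(c(1, 4), c(1, 5), c(2, 5), c(3, 4), c(4, 5))
    for (k in seq_along(nb_idx)) {
      grad <- add(grad, nb_idx[[k]][1], nb_idx[[k]][2],
                  -nb_e[k] / p$nb_rep_rho, nb_pairs[[k]]$u)
    }
    list(energy = energy, gradient = grad)
  }
}

# Minimize the toy energy at fixed xi (stiff harmonic RC restraint).
.toy_relax <- function(pot, p, xi, k_res = 5000, start = NULL) {
  coords0 <- start %||% .toy_geometry(p, xi)
  obj <- function(x) {
    co <- matrix(x, 5, 3)
    reg <- list(coordinates = co)
    out <- pot(reg)
    d_oc <- sqrt(sum((co[1, ] - co[2, ])^2))
    d_cc <- sqrt(sum((co[2, ] - co[3, ])^2))
    out$energy + k_res * (d_oc - d_cc - xi)^2
  }
  grr <- function(x) {
    co <- matrix(x, 5, 3)
    reg <- list(coordinates = co)
    out <- pot(reg)
    dv1 <- co[1, ] - co[2, ]; d_oc <- sqrt(sum(dv1^2))
    dv2 <- co[2, ] - co[3, ]; d_cc <- sqrt(sum(dv2^2))
    g <- out$gradient
    coef <- 2 * k_res * (d_oc - d_cc - xi)
    g[1, ] <- g[1, ] + coef * dv1 / d_oc
    g[2, ] <- g[2, ] - coef * dv1 / d_oc - coef * dv2 / d_cc
    g[3, ] <- g[3, ] + coef * dv2 / d_cc
    as.numeric(g)
  }
  fit <- stats::optim(as.numeric(coords0), obj, grr, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  matrix(fit$par, 5, 3)
}

# Relaxed 1D profile over a xi grid; locates minima and the barrier.
.toy_profile <- function(pot, p, xi_grid = seq(-1.4, 1.1, by = 0.05)) {
  energies <- numeric(length(xi_grid))
  start <- NULL
  for (k in seq_along(xi_grid)) {
    co <- .toy_relax(pot, p, xi_grid[k], start = start)
    start <- co
    energies[k] <- pot(list(coordinates = co))$energy
  }
  n <- length(energies)
  interior <- 2:(n - 1)
  is_min <- interior[energies[interior] < energies[interior - 1] &
                       energies[interior] <= energies[interior + 1]]
  if (length(is_min) < 2) {
    stop("toy profile is not a double well with these parameters",
         call. = FALSE)
  }
  i_r <- is_min[1]
  i_p <- is_min[length(is_min)]
  between <- i_r:i_p
  i_ts <- between[which.max(energies[between])]
  list(xi = xi_grid, energy = energies,
       rc_reactant = xi_grid[i_r], rc_product = xi_grid[i_p],
       rc_ts = xi_grid[i_ts],
       barrier = energies[i_ts] - energies[i_r],
       asymmetry = energies[i_p] - energies[i_r])
}

#' Relaxed gas-phase profile of the toy surface along its RC
#'
#' Constrained minimization of the surface at each grid value of
#' `xi = d(O1-C2) - d(C2-C3)`; used for calibration checks and as the
#' zero-temperature reference for PMF sanity checks.
#'
#' @param surface a [toy_reactive_surface()].
#' @param xi_grid RC grid (angstrom).
#' @return data.frame with `xi` and `energy` (kcal/mol).
#' @export
toy_gas_profile <- function(surface, xi_grid = seq(-1.4, 1.1, by = 0.05)) {
  prof <- .toy_profile(surface$fun, surface$params, xi_grid)
  data.frame(xi = prof$xi, energy = prof$energy)
}
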