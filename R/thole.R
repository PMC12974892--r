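#' Atomic polarizability model (fixed or environment-flexible ratios)
#'
#' Atomic polarizabilities are proportional to density-derived atomic
#' volumes, `alpha_i = k_Z(i) * v_i`, with one learnable ratio `k_Z` per
#' chemical element. In `flexible` mode an additional environment-dependent
#' correction factor `k_alpha` (a sparse GPR with prior mean 1 over the
#' atomic-environment descriptors) multiplies the ratio:
#' `alpha_i = k_alpha(G_i) * k_Z(i) * v_i`.
#'
#' @param k_z named numeric vector, element -> alpha/v ratio (> 0).
#' @param mode `"fixed"` or `"flexible"`.
#' @param k_alpha_model a [fit_sparse_gpr()] model with prior mean 1
#'   (required in flexible mode).
#' @param settings [descriptor_settings()] used by `k_alpha_model`.
#' @param thole_damping_a dimensionless Thole damping constant (exponential
#'   damping kernel); default 0.39.
#' @return an object of class `polarizability_model`.
#' @export
polarizability_model <- function(k_z, mode = c("fixed", "flexible"),
                                 k_alpha_model = NULL, settings = NULL,
                                 thole_damping_a = 0.39) {
  mode <- match.arg(mode)
  if (any(k_z <= 0)) stop("all k_Z ratios must be positive", call. = FALSE)
  if (is.null(names(k_z)) || any(!nzchar(names(k_z)))) {
    stop("k_z must be a named element -> ratio map", call. = FALSE)
  }
  if (mode == "flexible" && is.null(k_alpha_model)) {
    stop("flexible mode requires a k_alpha_model", call. = FALSE)
  }
  structure(list(k_z = k_z, mode = mode, k_alpha_model = k_alpha_model,
                 settings = settings, thole_damping_a = thole_damping_a),
            class = "polarizability_model")
}

#' @export
print.polarizability_model <- function(x, ...) {
  cat("polarizability_model [", x$mode, "]: k_Z =",
      paste(names(x$k_z), format(x$k_z, digits = 4), collapse = ", "),
      " damping a =", x$thole_damping_a, "\n")
  invisible(x)
}

#' Per-atom polarizabilities from volumes
#'
#' @param model a [polarizability_model()] (or a ground-truth backend
#'   implementing the same contract).
#' @param density a [density_parameters()] supplying volumes (bohr^3).
#' @param region the [ml_region()] (elements; descriptors in flexible mode).
#' @return per-atom polarizabilities (bohr^3).
#' @export
atomic_polarizabilities <- function(model, density, region) {
  UseMethod("atomic_polarizabilities")
}

#' @export
atomic_polarizabilities.polarizability_model <- function(model, density,
                                                         region) {
  el <- region$elements
  missing <- setdiff(unique(el), names(model$k_z))
  if (length(missing) > 0) {
    stop("element(s) missing from k_Z map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  alpha <- unname(model$k_z[el]) * density$volumes
  if (model$mode == "flexible") {
    feat <- compute_descriptors(region, model$settings)
    alpha <- alpha * predict(model$k_alpha_model, feat)
  }
  alpha
}

# Thole exponential damping factors for reduced distance u = d/(ai*aj)^(1/6):
# lambda3 = 1 - exp(-a u^3), lambda5 = 1 - (1 + a u^3) exp(-a u^3).
.thole_lambdas <- function(d, ai, aj, a) {
  x <- a * d^3 / sqrt(ai * aj)
  ex <- exp(-x)
  list(l3 = 1 - ex, l5 = 1 - (1 + x) * ex, x = x, ex = ex)
}

# Build the 3N x 3N Thole relay matrix A (bohr^-3 on the diagonal).
.relay_matrix <- function(coords_bohr, alphas, a) {
  n <- nrow(coords_bohr)
  A <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    bi <- (3 * i - 2):(3 * i)
    A[bi, bi] <- diag(1 / alphas[i], 3)
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- coords_bohr[i, ] - coords_bohr[j, ]
        d <- sqrt(sum(r^2))
        lam <- .thole_lambdas(d, alphas[i], alphas[j], a)
        t_ij <- lam$l5 * 3 * tcrossprod(r) / d^5 - lam$l3 * diag(3) / d^3
        bi <- (3 * i - 2):(3 * i)
        bj <- (3 * j - 2):(3 * j)
        A[bi, bj] <- -t_ij
        A[bj, bi] <- -t_ij
      }
    }
  }
  A
}

# Electric field (a.u.) at ML atom positions from MM point charges.
.mm_field <- function(region, env) {
  g <- .pair_geometry(region, env)
  qinv3 <- 1 / g$d^3
  q <- env$charges
  cbind(as.numeric((g$dx * qinv3) %*% q),
        as.numeric((g$dy * qinv3) %*% q),
        as.numeric((g$dz * qinv3) %*% q))
}

#' Solve the Thole induced-dipole equations
#'
#' Each ML atom is an isotropic polarizable center responding to the
#' external field of the MM point charges and to the fields of the dipoles
#' induced on the other ML atoms (damped dipole-dipole interactions). The
#' relay equations `A mu = E` are solved by direct dense factorization;
#' `E_induced = -1/2 sum_i mu_i . E_i <= 0` by linear response.
#'
#' @param alphas per-atom polarizabilities (bohr^3, > 0).
#' @param region an [ml_region()].
#' @param env an [mm_environment()]; alternatively `field` may be given.
#' @param field optional explicit per-atom external field (a.u.), replacing
#'   the MM-charge field (used for finite-field checks).
#' @param damping_a Thole damping constant.
#' @param gradient if `TRUE`, also return analytic gradients of `e_induced`
#'   with respect to ML and MM coordinates (polarizabilities held fixed),
#'   as forces in hartree/bohr.
#' @param solver `"direct"` (dense Cholesky, the reference path) or
#'   `"jacobi"` (damped fixed-point iteration; available as a cross-check,
#'   agrees with the direct solve to tight tolerance when it converges).
#' @return a list of class `induction_result`: `induced_dipoles` (n x 3,
#'   a.u.), `e_induced` (hartree), `external_field`, `alpha_atoms`, and
#'   forces when requested.
#' @export
solve_induction <- function(alphas, region, env = NULL, field = NULL,
                            damping_a = 0.39, gradient = FALSE,
                            solver = c("direct", "jacobi")) {
  solver <- match.arg(solver)
  if (any(alphas <= 0)) stop("all polarizabilities must be > 0", call. = FALSE)
  n <- n_atoms(region)
  coords_bohr <- region$coordinates / BOHR_TO_ANGSTROM
  if (is.null(field)) {
    if (is.null(env)) stop("either env or field must be given", call. = FALSE)
    field <- .mm_field(region, env)
  }
  A <- .relay_matrix(coords_bohr, alphas, damping_a)
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    stop("relay matrix not positive definite (overpolarization at short ",
         "range); closest pair: ", .closest_pair_label(region), call. = FALSE)
  }
  if (solver == "direct") {
    mu <- backsolve(ch, backsolve(ch, as.numeric(t(field)), transpose = TRUE))
  } else {
    # damped Jacobi fixed point: mu <- (1-w) mu + w alpha (E + T mu)
    e_flat <- as.numeric(t(field))
    alpha3 <- rep(alphas, each = 3)
    t_off <- -A
    diag(t_off) <- 0  # A off-diagonal blocks are -T
    mu <- alpha3 * e_flat
    w <- 0.5
    for (it in 1:10000) {
      mu_new <- (1 - w) * mu + w * alpha3 * (e_flat + as.numeric(t_off %*% mu))
      if (max(abs(mu_new - mu)) < 1e-12) {
        mu <- mu_new
        break
      }
      mu <- mu_new
    }
    if (it == 10000) {
      stop("Jacobi induction solver did not converge", call. = FALSE)
    }
  }
  mu_mat <- matrix(mu, ncol = 3, byrow = TRUE)
  e_ind <- -0.5 * sum(mu_mat * field)
  out <- structure(list(induced_dipoles = mu_mat, e_induced = e_ind,
                        external_field = field, alpha_atoms = alphas),
                   class = "induction_result")
  if (!gradient) return(out)
  if (is.null(env)) stop("gradient requires an MM environment", call. = FALSE)
  grads <- .induction_gradients(coords_bohr, alphas, mu_mat, region, env,
                                damping_a)
  out$forces_ml <- -grads$g_ml
  out$forces_mm <- -grads$g_mm
  out
}

.closest_pair_label <- function(region) {
  d <- as.matrix(stats::dist(region$coordinates))
  diag(d) <- Inf
  ij <- which(d == min(d), arr.ind = TRUE)[1, ]
  paste0(region$atom_labels[ij[1]], "-", region$atom_labels[ij[2]])
}

# Gradients of e_induced wrt ML and MM coordinates, alphas frozen.
# dE_ind = -dE^T mu - sum_{i<j} mu_i^T dT_ij mu_j.
.induction_gradients <- function(coords_bohr, alphas, mu, region, env, a) {
  n <- nrow(coords_bohr)
  g_ml <- matrix(0, n, 3)
  # field part: E_i depends on R_i and MM positions
  g <- .pair_geometry(region, env)
  nmm <- nrow(env$positions)
  g_mm <- matrix(0, nmm, 3)
  for (i in seq_len(n)) {
    d <- g$d[i, ]
    rv <- rbind(g$dx[i, ], g$dy[i, ], g$dz[i, ])  # 3 x nmm, R_i - r_j
    # dE_i/dR_i = sum_j q_j (I/d^3 - 3 r r^T / d^5)
    mdotr <- as.numeric(mu[i, ] %*% rv)
    coef <- env$charges / d^3
    coef5 <- 3 * env$charges * mdotr / d^5
    rv_c5 <- as.numeric(rv %*% coef5)
    # -mu_i^T dE_i/dR_i accumulated over MM atoms
    g_ml[i, ] <- g_ml[i, ] - (mu[i, ] * sum(coef) - rv_c5)
    # dE_i/dr_j = -q_j (I/d^3 - 3 r r^T/d^5): opposite sign per MM atom
    g_mm <- g_mm + outer(coef, mu[i, ]) - t(rv) * coef5
  }
  # dipole-dipole part
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        r <- coords_bohr[i, ] - coords_bohr[j, ]
        d <- sqrt(sum(r^2))
        lam <- .thole_lambdas(d, alphas[i], alphas[j], a)
        mir <- sum(mu[i, ] * r); mjr <- sum(mu[j, ] * r)
        mimj <- sum(mu[i, ] * mu[j, ])
        rhat <- r / d
        dg <- 3 * lam$l5 * (mjr * mu[i, ] + mir * mu[j, ]) / d^5 +
          3 * mir * mjr * rhat * (3 * lam$x^2 * lam$ex - 5 * lam$l5) / d^6 -
          3 * mimj * rhat * (lam$x * lam$ex - lam$l3) / d^4
        # contribution -grad_r (mu_i T mu_j); r = R_i - R_j
        g_ml[i, ] <- g_ml[i, ] - dg
        g_ml[j, ] <- g_ml[j, ] + dg
      }
    }
  }
  list(g_ml = g_ml, g_mm = g_mm)
}

#' Molecular polarizability tensor from the Thole relay
#'
#' `alpha_mol = sum_{ij} [A^{-1}]_{ij}` over 3x3 blocks of the inverse relay
#' matrix; the isotropic polarizability is a third of the trace.
#'
#' @param alphas per-atom polarizabilities (bohr^3).
#' @param region an [ml_region()].
#' @param damping_a Thole damping constant.
#' @return list with `tensor` (3 x 3, bohr^3) and `isotropic`.
#' @export
molecular_polarizability <- function(alphas, region, damping_a = 0.39) {
  n <- n_atoms(region)
  coords_bohr <- region$coordinates / BOHR_TO_ANGSTROM
  A <- .relay_matrix(coords_bohr, alphas, damping_a)
  B <- solve(A)
  tensor <- matrix(0, 3, 3)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tensor <- tensor + B[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)]
    }
  }
  tensor <- (tensor + t(tensor)) / 2
  list(tensor = tensor, isotropic = sum(diag(tensor)) / 3)
}

# Frobenius misfit of predicted vs reference molecular polarizability
# tensors for a list of conformers, given per-conformer volumes.
.polarizability_misfit <- function(alpha_fun, conformers, ref_tensors,
                                   damping_a) {
  total <- 0
  for (c in seq_along(conformers)) {
    alphas <- alpha_fun(c)
    pred <- molecular_polarizability(alphas, conformers[[c]], damping_a)$tensor
    total <- total + sum((pred - ref_tensors[[c]])^2)
  }
  total
}

#' Fit per-element polarizability/volume ratios
#'
#' Least-squares fit of the `k_Z` map minimizing the Frobenius misfit of
#' predicted versus reference molecular polarizability tensors over a set of
#' conformers. Deterministic (quasi-Newton from unit ratios, log
#' parametrization).
#'
#' @param ref_tensors list of reference 3x3 tensors (bohr^3), one per
#'   conformer.
#' @param conformers list of [ml_region()] objects.
#' @param volumes list (or matrix) of per-atom volumes (bohr^3) per
#'   conformer.
#' @param damping_a Thole damping constant (must match the reference
#'   convention).
#' @return named numeric `k_Z` map.
#' @export
fit_kz <- function(ref_tensors, conformers, volumes, damping_a = 0.39) {
  elements <- sort(unique(unlist(lapply(conformers, `[[`, "elements"))))
  vol_list <- if (is.list(volumes)) volumes else split(volumes, row(volumes))
  obj <- function(logk) {
    kz <- stats::setNames(exp(logk), elements)
    .polarizability_misfit(function(c) {
      unname(kz[conformers[[c]]$elements]) * vol_list[[c]]
    }, conformers, ref_tensors, damping_a)
  }
  fit <- stats::nlminb(rep(0, length(elements)), obj,
                       control = list(rel.tol = 1e-14, abs.tol = 0,
                                      x.tol = 1e-12, iter.max = 500))
  stats::setNames(exp(fit$par), elements)
}

#' Fit the environment-flexible polarizability correction
#'
#' Fits the `k_alpha` sparse-GPR correction (prior mean 1) by penalized
#' least squares against molecular polarizability tensors: for every
#' conformer the per-atom correction factors minimizing the Frobenius
#' tensor misfit plus `lambda * sum (k_alpha - 1)^2` are recovered by a
#' damped Gauss-Newton inversion (the unity bias keeps the inversion
#' stable; without it the correction overfits and destabilizes subsequent
#' dynamics), and the recovered factors are then regressed on the atomic
#' descriptors with a sparse GPR whose prior mean is 1. The two-stage
#' scheme avoids the near-degenerate directions of a joint field fit on
#' nearly axially symmetric conformers. Deterministic given the seed
#' (inducing points by farthest-point sampling over the pooled atomic
#' descriptors).
#'
#' @param ref_tensors list of reference 3x3 tensors (bohr^3).
#' @param conformers list of [ml_region()] objects.
#' @param volumes per-conformer per-atom volumes (bohr^3).
#' @param k_z fixed-model `k_Z` map (e.g. from [fit_kz()]).
#' @param settings [descriptor_settings()] for the correction model.
#' @param lambda regularization weight (>= 0) on `(k_alpha - 1)^2`.
#' @param n_inducing inducing points for the correction GPR.
#' @param lengthscale,variance kernel hyperparameters.
#' @param noise_variance regression noise floor smoothing the inverted
#'   factors.
#' @param damping_a Thole damping constant.
#' @param seed integer seed.
#' @return a `polarizability_model` in flexible mode.
#' @export
fit_flexible_alpha <- function(ref_tensors, conformers, volumes, k_z,
                               settings, lambda = 1e-3, n_inducing = 48L,
                               lengthscale = NULL, variance = 1.0,
                               noise_variance = 1e-4, damping_a = 0.39,
                               seed = 1L) {
  vol_list <- if (is.list(volumes)) volumes else split(volumes, row(volumes))
  feats <- lapply(conformers, compute_descriptors, settings = settings)
  pooled <- do.call(rbind, feats)
  if (is.null(lengthscale)) {
    rows <- unique(round(seq(1, nrow(pooled),
                             length.out = min(200, nrow(pooled)))))
    d <- stats::dist(pooled[rows, , drop = FALSE])
    lengthscale <- max(stats::median(d) / 2, 1e-3)
  }
  # stage 1: per-conformer penalized tensor inversion for the correction
  targets <- vector("list", length(conformers))
  for (c in seq_along(conformers)) {
    base <- unname(k_z[conformers[[c]]$elements]) * vol_list[[c]]
    targets[[c]] <- .invert_kalpha(base, conformers[[c]], ref_tensors[[c]],
                                   lambda, damping_a)
  }
  # stage 2: sparse GPR (prior mean 1) of the recovered factors
  ka_model <- fit_sparse_gpr(pooled, unlist(targets),
                             n_inducing = min(n_inducing, nrow(pooled)),
                             lengthscale = lengthscale, variance = variance,
                             noise_variance = noise_variance, seed = seed,
                             prior_mean = 1)
  polarizability_model(k_z, mode = "flexible", k_alpha_model = ka_model,
                       settings = settings, thole_damping_a = damping_a)
}

# Damped Gauss-Newton inversion of one conformer's molecular polarizability
# tensor for the per-atom correction factors (unity-biased).
.invert_kalpha <- function(base_alpha, region, ref_tensor, lambda,
                           damping_a) {
  n <- length(base_alpha)
  iu <- which(upper.tri(matrix(0, 3, 3), diag = TRUE))
  resid <- function(ka) {
    pred <- molecular_polarizability(base_alpha * pmax(ka, 1e-3), region,
                                     damping_a)$tensor
    c((pred - ref_tensor)[iu], sqrt(lambda) * (ka - 1))
  }
  ka <- rep(1, n)
  r0 <- resid(ka)
  for (it in 1:40) {
    h <- 1e-6
    jac <- vapply(seq_len(n), function(k) {
      kp <- ka; kp[k] <- kp[k] + h
      (resid(kp) - r0) / h
    }, numeric(length(r0)))
    step <- tryCatch(qr.solve(jac, -r0), error = function(e) NULL)
    if (is.null(step)) break
    tfac <- 1
    repeat {
      r1 <- resid(ka + tfac * step)
      if (sum(r1^2) <= sum(r0^2) || tfac < 1e-4) break
      tfac <- tfac / 2
    }
    improved <- sum(r0^2) - sum(r1^2)
    ka <- pmax(ka + tfac * step, 1e-3)
    r0 <- r1
    if (improved < 1e-18 * (1 + sum(r0^2))) break
  }
  ka
}
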