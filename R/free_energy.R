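#' Build an inclusive umbrella-window grid
#'
#' Centers run from `rc_min` to `rc_max` inclusive with the given spacing;
#' the count is `round((rc_max - rc_min)/spacing) + 1`, and endpoints must
#' sit on the lattice to within 1e-9.
#'
#' @param rc_min,rc_max first and last window center (angstrom).
#' @param spacing center spacing (angstrom, > 0).
#' @param force_constant umbrella force constant (kcal/mol/A^2, engine
#'   convention `K (xi - xi0)^2`).
#' @return an object of class `window_grid` with a `centers` field.
#' @examples
#' length(make_window_grid(1.3, 3.8, 0.1)$centers)   # 26
#' length(make_window_grid(-4.5, 2.2, 0.1)$centers)  # 68
#' @export
make_window_grid <- function(rc_min, rc_max, spacing, force_constant = 100) {
  if (spacing <= 0) stop("spacing must be > 0", call. = FALSE)
  count <- round((rc_max - rc_min) / spacing) + 1
  if (count < 1) stop("rc_max must be >= rc_min", call. = FALSE)
  if (abs((rc_min + (count - 1) * spacing) - rc_max) > 1e-9) {
    stop("grid endpoints are not on the spacing lattice", call. = FALSE)
  }
  centers <- rc_min + spacing * (seq_len(count) - 1)
  structure(list(rc_min = rc_min, rc_max = rc_max, spacing = spacing,
                 centers = centers, force_constant = force_constant),
            class = "window_grid")
}

#' @export
print.window_grid <- function(x, ...) {
  cat("window_grid:", length(x$centers), "windows from", x$rc_min, "to",
      x$rc_max, "A (spacing", x$spacing, "A, K =", x$force_constant,
      "kcal/mol/A^2)\n")
  invisible(x)
}

# Deterministic per-(window, replica) seed derived from the master seed.
.window_seed <- function(seed, window, replica) {
  as.integer((as.double(seed) * 7919 + window * 104729 + replica * 1299709) %%
               2147483587)
}

#' Run umbrella sampling over a window grid
#'
#' For each window and replica, Langevin dynamics under the unbiased forces
#' plus the harmonic window bias `K (xi - center)^2`; RC samples are
#' recorded after equilibration. Deterministic per (window, replica, seed).
#'
#' @param windows a [make_window_grid()].
#' @param force_fun unbiased force field: function(region) ->
#'   list(energy, forces) (kcal/mol, kcal/mol/A).
#' @param init_fun function(center) -> starting [ml_region()] for a window.
#' @param rc the sampled [reaction_coordinate()].
#' @param replicas number of independent replicas per window.
#' @param steps_per_window production steps per window and replica.
#' @param equilibration_steps discarded steps before production.
#' @param dt_fs timestep (fs).
#' @param temperature kelvin.
#' @param friction_fs Langevin friction (1/fs).
#' @param sample_stride record the RC every this many steps.
#' @param masses optional per-atom masses (amu) forwarded to
#'   [run_langevin()] (element defaults otherwise).
#' @param continuation if `TRUE`, each window starts from the previous
#'   window's final configuration instead of a fresh `init_fun` structure.
#'   Replica chains are independent and alternate traversal direction
#'   (replica 1 walks the grid upward, replica 2 downward, ...), so with
#'   two or more replicas every window is approached from both sides of
#'   the profile. This removes the histogram gaps that arise when the
#'   combined bias plus free-energy surface is bistable near a barrier top
#'   and independently initialized windows fall to one side.
#' @param seed master seed.
#' @return data.frame `(window_center, replica, step, rc_value)` with
#'   attributes `windows`, `temperature` and `non_overlapping` (window
#'   centers whose samples never entered 3 thermal widths of the center).
#' @export
run_umbrella <- function(windows, force_fun, init_fun, rc,
                         replicas = 1L, steps_per_window = 2000L,
                         equilibration_steps = 200L, dt_fs = 0.5,
                         temperature = 300, friction_fs = 0.02,
                         sample_stride = 5L, masses = NULL,
                         continuation = FALSE, seed = 1L) {
  out <- list()
  kt <- KB_KCALMOL * temperature
  sigma_expect <- sqrt(kt / (2 * windows$force_constant))
  nw <- length(windows$centers)
  entered <- logical(nw)
  for (r in seq_len(replicas)) {
    order_w <- if (continuation && r %% 2 == 0) rev(seq_len(nw)) else
      seq_len(nw)
    chain <- NULL
    for (w in order_w) {
      center <- windows$centers[w]
      bias <- restraint("harmonic_rc", rc = rc, target = center,
                        force_constant = windows$force_constant)
      biased <- function(region) {
        f <- force_fun(region)
        b <- restraint_energy(bias, region)
        list(energy = f$energy + b$energy, forces = f$forces + b$forces)
      }
      region <- if (continuation && !is.null(chain)) chain else
        init_fun(center)
      rc_values <- numeric(0)
      rec <- function(step, reg, vel, en) {
        if (step > equilibration_steps &&
            (step - equilibration_steps) %% sample_stride == 0) {
          rc_values[[length(rc_values) + 1L]] <<- evaluate_rc(rc, reg)
        }
      }
      fin <- run_langevin(biased, region, dt_fs = dt_fs,
                          n_steps = equilibration_steps + steps_per_window,
                          temperature = temperature,
                          friction_fs = friction_fs, masses = masses,
                          seed = .window_seed(seed, w, r), record = rec)
      if (continuation) chain <- fin$region
      rc_values <- unlist(rc_values)
      if (any(abs(rc_values - center) < 3 * sigma_expect)) {
        entered[w] <- TRUE
      }
      out[[length(out) + 1L]] <- data.frame(
        window_center = center, replica = r,
        step = seq_along(rc_values) * sample_stride,
        rc_value = rc_values)
    }
  }
  flagged <- windows$centers[!entered]
  res <- do.call(rbind, out)
  res <- res[order(match(res$window_center, windows$centers), res$replica), ]
  rownames(res) <- NULL
  attr(res, "windows") <- windows
  attr(res, "temperature") <- temperature
  attr(res, "non_overlapping") <- flagged
  res
}

#' Weighted histogram analysis of umbrella-sampling data
#'
#' Self-consistent binned WHAM: iterates the window free energies until the
#' largest change is below `tolerance`, then reports the unbiased PMF
#' shifted so its minimum is zero. The bias convention matches the
#' restraint convention (`K (xi - c)^2`, no 1/2, unless `half_convention`).
#'
#' @param samples data.frame with `window_center` and `rc_value` columns
#'   (e.g. from [run_umbrella()]).
#' @param windows the [make_window_grid()] used for sampling.
#' @param temperature kelvin.
#' @param bin_width histogram bin width (angstrom); default spacing/5.
#' @param tolerance convergence threshold on window free energies
#'   (kcal/mol).
#' @param max_iter iteration cap.
#' @param half_convention bias uses `K/2 (xi - c)^2` when `TRUE`.
#' @return an object of class `pmf_profile`: `rc_grid`, `free_energy`
#'   (kcal/mol, minimum at 0), `std` (NA here; see [pmf_uncertainty()]),
#'   `temperature`, `metadata`.
#' @export
wham <- function(samples, windows, temperature = 300, bin_width = NULL,
                 tolerance = 1e-6, max_iter = 100000L,
                 half_convention = FALSE) {
  if (is.null(bin_width)) bin_width <- windows$spacing / 5
  kt <- KB_KCALMOL * temperature
  pref <- if (half_convention) 0.5 else 1.0
  centers_w <- sort(unique(samples$window_center))
  rng <- range(samples$rc_value)
  edges <- seq(rng[1] - 1e-9, rng[2] + bin_width, by = bin_width)
  mids <- edges[-1] - bin_width / 2
  nb <- length(mids)
  nw <- length(centers_w)
  counts <- matrix(0, nw, nb)
  for (k in seq_len(nw)) {
    x <- samples$rc_value[samples$window_center == centers_w[k]]
    counts[k, ] <- tabulate(findInterval(x, edges, all.inside = TRUE), nb)
  }
  occupied <- colSums(counts) > 0
  if (nw >= 2) {
    for (k in seq_len(nw - 1)) {
      if (!any(counts[k, ] > 0 & counts[k + 1, ] > 0)) {
        stop("non-overlapping histograms between windows at ",
             centers_w[k], " and ", centers_w[k + 1], " A", call. = FALSE)
      }
    }
  }
  nk <- rowSums(counts)
  bias <- pref * windows$force_constant *
    outer(centers_w, mids, function(c, x) (x - c)^2)
  ebias <- exp(-bias / kt)
  f <- numeric(nw)
  nbin_tot <- colSums(counts)
  for (iter in seq_len(max_iter)) {
    ef <- exp(f / kt)
    denom <- colSums(nk * ebias * ef)
    p <- ifelse(occupied, nbin_tot / denom, 0)
    f_new <- -kt * log(pmax(ebias %*% p, .Machine$double.xmin))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    if (!is.finite(delta)) {
      stop("WHAM iteration diverged (non-finite window free energies); ",
           "check for outlier samples or missing window overlap",
           call. = FALSE)
    }
    f <- as.numeric(f_new)
    if (delta < tolerance) break
  }
  if (delta >= tolerance) {
    stop("WHAM did not converge: residual ", format(delta, digits = 4),
         " kcal/mol after ", max_iter, " iterations", call. = FALSE)
  }
  pmf <- -kt * log(p[occupied])
  pmf <- pmf - min(pmf)
  structure(list(rc_grid = mids[occupied], free_energy = pmf,
                 std = rep(NA_real_, sum(occupied)),
                 temperature = temperature,
                 metadata = list(windows = windows, bin_width = bin_width,
                                 iterations = iter,
                                 window_free_energies = f)),
            class = "pmf_profile")
}

#' @export
print.pmf_profile <- function(x, ...) {
  cat("pmf_profile:", length(x$rc_grid), "points, RC",
      format(min(x$rc_grid), digits = 3), "to",
      format(max(x$rc_grid), digits = 3), "A, max",
      format(max(x$free_energy), digits = 4), "kcal/mol at",
      x$temperature, "K\n")
  invisible(x)
}

#' Activation and reaction free energies from a PMF
#'
#' The activation free energy is the profile maximum between the basins
#' minus the reactant-basin minimum; the reaction free energy is the
#' product-basin minimum minus the reactant-basin minimum. Basin ranges are
#' explicit; there is no automatic basin detection.
#'
#' @param profile a [wham()] `pmf_profile`.
#' @param reactant_range,product_range length-2 RC intervals (angstrom).
#' @param ts_range optional explicit interval to search for the barrier
#'   top; default is the interval between the basin ranges.
#' @return list with `barrier` (activation free energy), `reaction`
#'   (reaction free energy), and the locations `rc_reactant`, `rc_ts`,
#'   `rc_product`.
#' @export
pmf_statistics <- function(profile, reactant_range, product_range,
                           ts_range = NULL) {
  x <- profile$rc_grid
  y <- profile$free_energy
  pick <- function(range) {
    sel <- which(x >= min(range) & x <= max(range))
    if (length(sel) == 0) stop("no PMF points in range [",
                               min(range), ", ", max(range), "]",
                               call. = FALSE)
    sel
  }
  ir <- pick(reactant_range)
  ip <- pick(product_range)
  i_rmin <- ir[which.min(y[ir])]
  i_pmin <- ip[which.min(y[ip])]
  user_ts <- !is.null(ts_range)
  if (!user_ts) {
    ts_range <- sort(c(max(reactant_range), min(product_range)))
  }
  it <- pick(ts_range)
  i_ts <- it[which.max(y[it])]
  if (!user_ts && length(it) > 2 && (i_ts == min(it) || i_ts == max(it))) {
    stop("no interior barrier maximum found between the basins; give an ",
         "explicit ts_range", call. = FALSE)
  }
  list(barrier = y[i_ts] - y[i_rmin],
       reaction = y[i_pmin] - y[i_rmin],
       rc_reactant = x[i_rmin], rc_ts = x[i_ts], rc_product = x[i_pmin])
}

#' Catalytic effect between two environments
#'
#' `ddG = barrier(B) - barrier(A)`; negative values mean environment B
#' (e.g. the enzyme) catalyzes relative to A (e.g. water).
#'
#' @param barrier_env_a,barrier_env_b activation free energies (kcal/mol).
#' @return the catalytic effect (kcal/mol).
#' @examples
#' catalytic_effect(23.3, 10.8)  # -12.5
#' @export
catalytic_effect <- function(barrier_env_a, barrier_env_b) {
  barrier_env_b - barrier_env_a
}

#' PMF uncertainty from replicas or time fragments
#'
#' `"replica"` recomputes one PMF per replica and reports the per-point
#' standard deviation across replicas. `"fragment"` splits every window's
#' time series into `n_fragments` contiguous fragments and recomputes one
#' PMF per fragment index (the 5-fragment variant is the default). When
#' basin ranges are given, derived barrier/reaction energies and their
#' standard deviations across recomputations are reported as well.
#'
#' @param samples umbrella samples (`window_center`, `replica`, `step`,
#'   `rc_value`).
#' @param windows the [make_window_grid()].
#' @param temperature kelvin.
#' @param method `"replica"` or `"fragment"`.
#' @param n_fragments fragments per window (fragment method).
#' @param reactant_range,product_range,ts_range optional; see
#'   [pmf_statistics()].
#' @param ... passed to [wham()].
#' @return list with `profile` (mean PMF with per-point `std`), `profiles`
#'   (the recomputed PMFs), and when ranges are given `barrier`,
#'   `barrier_sd`, `reaction`, `reaction_sd`.
#' @export
pmf_uncertainty <- function(samples, windows, temperature = 300,
                            method = c("replica", "fragment"),
                            n_fragments = 5L, reactant_range = NULL,
                            product_range = NULL, ts_range = NULL, ...) {
  method <- match.arg(method)
  groups <- if (method == "replica") {
    lapply(sort(unique(samples$replica)),
           function(r) samples[samples$replica == r, ])
  } else {
    lapply(seq_len(n_fragments), function(fr) {
      keep <- rep(FALSE, nrow(samples))
      for (c in unique(samples$window_center)) {
        for (r in unique(samples$replica)) {
          sel <- which(samples$window_center == c & samples$replica == r)
          sel <- sel[order(samples$step[sel])]
          cuts <- floor(seq(0, length(sel), length.out = n_fragments + 1))
          if (cuts[fr + 1] > cuts[fr]) {
            keep[sel[(cuts[fr] + 1):cuts[fr + 1]]] <- TRUE
          }
        }
      }
      samples[keep, ]
    })
  }
  profiles <- lapply(groups, wham, windows = windows,
                     temperature = temperature, ...)
  # common grid: interpolate each PMF onto the grid of the first
  grid <- profiles[[1]]$rc_grid
  mat <- vapply(profiles, function(p) {
    stats::approx(p$rc_grid, p$free_energy, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  mean_pmf <- rowMeans(mat)
  mean_pmf <- mean_pmf - min(mean_pmf)
  std <- apply(mat, 1, stats::sd)
  profile <- structure(list(rc_grid = grid, free_energy = mean_pmf,
                            std = std, temperature = temperature,
                            metadata = list(method = method,
                                            n_recomputations = length(groups))),
                       class = "pmf_profile")
  out <- list(profile = profile, profiles = profiles)
  if (!is.null(reactant_range) && !is.null(product_range)) {
    stats <- lapply(profiles, pmf_statistics, reactant_range = reactant_range,
                    product_range = product_range, ts_range = ts_range)
    b <- vapply(stats, `[[`, numeric(1), "barrier")
    rx <- vapply(stats, `[[`, numeric(1), "reaction")
    out$barrier <- mean(b)
    out$barrier_sd <- stats::sd(b)
    out$reaction <- mean(rx)
    out$reaction_sd <- stats::sd(rx)
  }
  out
}
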