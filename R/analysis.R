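#' Per-structure decomposition of model error into energy components
#'
#' For each structure, evaluates the model's gas, static and induced
#' components and subtracts the reference values. The reference induced
#' energy is reconstructed as
#' `e_total_ref - e_gas_ref - e_static_ref - e_mm_ref` (zero `e_mm_ref`
#' when the column is absent), mirroring how the induced component is
#' defined for an embedded reference calculation. All energies kcal/mol.
#'
#' @param structures list of [ml_region()] objects.
#' @param environments one [mm_environment()] or a list, one per structure.
#' @param reference data.frame with `frame_id`, `e_gas_ref`,
#'   `e_static_ref`, `e_total_ref`, optional `e_mm_ref` and `window`.
#' @param gas a [gas_phase_potential()].
#' @param static a [static_model()] or ground-truth backend.
#' @param pol a [polarizability_model()] or ground-truth backend.
#' @param variant an [embedding_variant()].
#' @param ml_lj optional `list(sigma, epsilon)` for the LJ term.
#' @return data.frame `(frame_id, [window,] d_gas, d_static, d_induced,
#'   d_total)`, one row per structure.
#' @export
component_errors <- function(structures, environments, reference,
                             gas, static, pol,
                             variant = embedding_variant("emle"),
                             ml_lj = NULL) {
  if (inherits(environments, "mm_environment")) {
    environments <- rep(list(environments), length(structures))
  }
  stopifnot(length(environments) == length(structures))
  ord <- match(seq_along(structures), reference$frame_id)
  if (anyNA(ord)) stop("reference table is missing frame ids", call. = FALSE)
  e_mm_ref <- if ("e_mm_ref" %in% names(reference)) {
    reference$e_mm_ref[ord]
  } else rep(0, length(structures))
  e_ind_ref <- induced_from_reference(reference$e_total_ref[ord] - e_mm_ref,
                                      reference$e_gas_ref[ord],
                                      reference$e_static_ref[ord])
  rows <- lapply(seq_along(structures), function(i) {
    dec <- total_energy(structures[[i]], environments[[i]], gas, static,
                        pol, variant, ml_lj = ml_lj)
    data.frame(frame_id = i,
               d_gas = dec$e_gas - reference$e_gas_ref[ord[i]],
               d_static = dec$e_static - reference$e_static_ref[ord[i]],
               d_induced = dec$e_induced - e_ind_ref[i],
               d_total = dec$e_total - reference$e_total_ref[ord[i]] -
                 (dec$e_mm - e_mm_ref[i]))
  })
  out <- do.call(rbind, rows)
  if ("window" %in% names(reference)) out$window <- reference$window[ord]
  out
}

#' Mean component errors per umbrella window
#'
#' @param errors output of [component_errors()] with a `window` column.
#' @return data.frame of per-window mean errors, ordered by window.
#' @export
window_mean_errors <- function(errors) {
  if (!"window" %in% names(errors)) {
    stop("errors table has no window column", call. = FALSE)
  }
  agg <- stats::aggregate(errors[c("d_gas", "d_static", "d_induced",
                                   "d_total")],
                          by = list(window = errors$window), FUN = mean)
  agg[order(agg$window), ]
}

#' Smooth an error curve with a cubic smoothing spline
#'
#' Presentation smoothing for per-window error curves; the raw data are
#' always retained alongside the smoothed values. A smoothing parameter of
#' 0 gives the interpolating spline through all points; by default the
#' smoothing level is chosen by generalized cross-validation.
#'
#' @param x,y the series to smooth.
#' @param spar smoothing parameter in `[0, 1]` passed to
#'   [stats::smooth.spline()]; `0` interpolates; `NULL` (default) selects
#'   by GCV.
#' @param n_out number of output points (evenly spaced over `range(x)`).
#' @return data.frame `(x, y_smooth)` plus attributes `x_raw`, `y_raw`.
#' @export
smooth_curve <- function(x, y, spar = NULL, n_out = length(x)) {
  stopifnot(length(x) == length(y))
  xo <- seq(min(x), max(x), length.out = n_out)
  if (!is.null(spar) && spar == 0) {
    ys <- stats::spline(x, y, xout = xo)$y
  } else {
    fit <- if (is.null(spar)) {
      stats::smooth.spline(x, y)
    } else {
      stats::smooth.spline(x, y, spar = spar)
    }
    ys <- stats::predict(fit, xo)$y
  }
  out <- data.frame(x = xo, y_smooth = ys)
  attr(out, "x_raw") <- x
  attr(out, "y_raw") <- y
  out
}

#' Radial distribution function for finite (non-periodic) systems
#'
#' Histogram of center-partner distances normalized by the spherical shell
#' volume `4 pi r^2 dr` and the mean partner density within `r_max`
#' (droplet normalization: the reference density is taken from the full
#' sampled sphere, since there is no periodic box). The
#' `"min_distance"` mode histograms each partner's minimum distance to any
#' center atom ("RDF around the substrate").
#'
#' @param frames list of frames; each frame is a list with `centers` (n x 3
#'   matrix) and `partners` (m x 3 matrix), angstrom.
#' @param bin_width histogram bin (angstrom).
#' @param r_max maximum distance.
#' @param mode `"all_pairs"` or `"min_distance"`.
#' @return data.frame `(r, g)` with bin centers and g(r).
#' @export
rdf <- function(frames, bin_width = 0.1, r_max = 10,
                mode = c("all_pairs", "min_distance")) {
  mode <- match.arg(mode)
  if (length(frames) < 1) stop("need at least one frame", call. = FALSE)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1
  counts <- numeric(nb)
  n_ref <- 0
  for (fr in frames) {
    cen <- as.matrix(fr$centers)
    par <- as.matrix(fr$partners)
    d2 <- outer(rowSums(cen^2), rowSums(par^2), "+") - 2 * tcrossprod(cen, par)
    d <- sqrt(pmax(d2, 0))
    dd <- if (mode == "all_pairs") as.numeric(d) else apply(d, 2, min)
    n_ref <- n_ref + if (mode == "all_pairs") nrow(cen) else 1
    dd <- dd[dd < r_max & dd > 0]
    counts <- counts + tabulate(findInterval(dd, edges, all.inside = TRUE), nb)
  }
  mids <- edges[-1] - bin_width / 2
  # droplet normalization: mean partner density from the full r_max sphere
  rho <- sum(counts) / (n_ref * (4 / 3) * pi * r_max^3)
  shell <- 4 * pi * mids^2 * bin_width
  g <- counts / (n_ref * shell * rho)
  data.frame(r = mids, g = g)
}
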