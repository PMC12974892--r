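#' Settings for the radial atomic-environment descriptor
#'
#' Per-atom feature vectors are element-resolved Gaussian radial sums with a
#' smooth cosine cutoff. They are invariant under rotation, translation, and
#' permutation of like atoms, and see only the ML region: the MM environment
#' is never visible to the descriptor.
#'
#' @param cutoff_radius environment radius in angstrom (> 0).
#' @param n_radial number of radial basis centers (>= 1), evenly spaced on
#'   (0, cutoff].
#' @param gaussian_width radial Gaussian width in angstrom.
#' @param element_vocabulary ordered, duplicate-free element list; every
#'   element a described region may contain must appear here.
#' @return an object of class `descriptor_settings`.
#' @export
descriptor_settings <- function(cutoff_radius = 5.0, n_radial = 16L,
                                gaussian_width = 0.5,
                                element_vocabulary = c("H", "C", "N", "O", "S")) {
  if (cutoff_radius <= 0) stop("cutoff_radius must be > 0", call. = FALSE)
  if (n_radial < 1) stop("n_radial must be >= 1", call. = FALSE)
  if (gaussian_width <= 0) stop("gaussian_width must be > 0", call. = FALSE)
  element_vocabulary <- as.character(element_vocabulary)
  if (length(element_vocabulary) == 0 || anyDuplicated(element_vocabulary)) {
    stop("element_vocabulary must be non-empty and duplicate-free", call. = FALSE)
  }
  structure(list(cutoff_radius = cutoff_radius,
                 n_radial = as.integer(n_radial),
                 gaussian_width = gaussian_width,
                 element_vocabulary = element_vocabulary),
            class = "descriptor_settings")
}

# Radial basis centers, evenly spaced on (0, cutoff].
.descriptor_centers <- function(settings) {
  rc <- settings$cutoff_radius
  k <- settings$n_radial
  seq(rc / k, rc, length.out = k)
}

#' Compute per-atom environment descriptors
#'
#' For atom `i`, feature `(Z, k)` is
#' `sum_{j != i, Z_j = Z} exp(-(d_ij - mu_k)^2 / (2 w^2)) * f_c(d_ij)` with
#' cosine cutoff `f_c(d) = (cos(pi d / r_c) + 1) / 2` for `d <= r_c`, else 0.
#' Feature length is `|vocabulary| * n_radial`.
#'
#' @param region an [ml_region()].
#' @param settings a [descriptor_settings()].
#' @return numeric matrix, one row per atom; columns named `Z.k`.
#' @export
compute_descriptors <- function(region, settings) {
  stopifnot(inherits(region, "ml_region"),
            inherits(settings, "descriptor_settings"))
  voc <- settings$element_vocabulary
  unknown <- setdiff(unique(region$elements), voc)
  if (length(unknown) > 0) {
    stop("element(s) not in descriptor vocabulary: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- n_atoms(region)
  mu <- .descriptor_centers(settings)
  w <- settings$gaussian_width
  rc <- settings$cutoff_radius
  feat <- matrix(0, n, length(voc) * settings$n_radial)
  colnames(feat) <- as.vector(outer(seq_len(settings$n_radial), voc,
                                    function(k, z) paste0(z, ".", k)))
  if (n < 2) return(feat)
  coords <- region$coordinates
  dmat <- as.matrix(stats::dist(coords))
  for (i in seq_len(n)) {
    d <- dmat[i, -i]
    el <- region$elements[-i]
    keep <- d < rc
    if (!any(keep)) next
    d <- d[keep]
    el <- el[keep]
    fc <- 0.5 * (cos(pi * d / rc) + 1)
    # n_neigh x n_radial Gaussian matrix, then element-channel row sums
    gm <- exp(-outer(d, mu, "-")^2 / (2 * w^2)) * fc
    for (z in unique(el)) {
      zi <- match(z, voc)
      cols <- ((zi - 1) * settings$n_radial + 1):(zi * settings$n_radial)
      feat[i, cols] <- colSums(gm[el == z, , drop = FALSE])
    }
  }
  feat
}
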