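#' Sparse Gaussian-process regression of per-atom scalar properties
#'
#' A subset-of-regressors (projected-process) sparse GP with an RBF kernel
#' `k(x, x') = s2 * exp(-||x - x'||^2 / (2 l^2))`, inducing points chosen by
#' deterministic farthest-point sampling (the seed selects the starting
#' point), and a fixed prior mean (the target mean by default). With
#' `n_inducing = n_samples` and vanishing noise it reproduces the dense GP
#' interpolator.
#'
#' @param features numeric sample x feature matrix.
#' @param targets numeric vector of property values.
#' @param n_inducing number of inducing points (<= number of samples).
#' @param lengthscale RBF kernel lengthscale (> 0).
#' @param variance RBF kernel variance (> 0).
#' @param noise_variance observation noise variance (>= 0).
#' @param seed integer seed for the inducing-point start.
#' @param prior_mean prior mean; defaults to `mean(targets)`.
#' @return an object of class `sparse_gpr`.
#' @export
fit_sparse_gpr <- function(features, targets, n_inducing,
                           lengthscale = 1.0, variance = 1.0,
                           noise_variance = 1e-8, seed = 1L,
                           prior_mean = NULL) {
  features <- as.matrix(features)
  targets <- as.numeric(targets)
  n <- nrow(features)
  if (length(targets) != n) stop("features/targets misaligned", call. = FALSE)
  if (n_inducing > n) stop("n_inducing exceeds sample count", call. = FALSE)
  if (lengthscale <= 0 || variance <= 0) {
    stop("kernel hyperparameters must be positive", call. = FALSE)
  }
  spread <- max(apply(features, 2, function(x) diff(range(x))))
  if (spread < 1e-12 && n > 1) {
    stop("degenerate features: all samples identical; consider a larger ",
         "descriptor cutoff or more radial channels", call. = FALSE)
  }
  if (is.null(prior_mean)) prior_mean <- mean(targets)
  idx <- .farthest_point_sample(features, n_inducing, seed)
  xm <- features[idx, , drop = FALSE]
  kmm <- .rbf_kernel(xm, xm, lengthscale, variance)
  kmn <- .rbf_kernel(xm, features, lengthscale, variance)
  y0 <- targets - prior_mean
  weights <- .sor_weights(kmm, kmn, y0, noise_variance)
  structure(list(inducing_points = xm,
                 weights = as.numeric(weights),
                 kernel_lengthscale = lengthscale,
                 kernel_variance = variance,
                 noise_variance = noise_variance,
                 prior_mean = prior_mean,
                 inducing_index = idx),
            class = "sparse_gpr")
}

# Subset-of-regressors weights, solved in augmented least-squares form
# (QR) rather than through the normal equations, which would square the
# condition number of the kernel matrix:
#   min ||K_nm w - y||^2 + noise * w' K_mm w
.sor_weights <- function(kmm, kmn, y0, noise_variance) {
  m <- nrow(kmm)
  if (noise_variance > 0) {
    scale <- mean(diag(kmm))
    jitter <- 1e-12 * scale
    umm <- NULL
    for (k in 1:9) {
      umm <- tryCatch(chol(kmm + diag(jitter, m)), error = function(e) NULL)
      if (!is.null(umm)) break
      jitter <- jitter * 100
    }
    if (is.null(umm)) {
      stop("inducing-point kernel matrix is numerically singular",
           call. = FALSE)
    }
    a <- rbind(t(kmn), sqrt(noise_variance) * umm)
    b <- c(y0, numeric(m))
  } else {
    a <- t(kmn)
    b <- y0
  }
  w <- qr.coef(qr(a, LAPACK = TRUE), b)
  w[is.na(w)] <- 0   # rank-deficient directions carry no weight
  w
}

.rbf_kernel <- function(x, y, lengthscale, variance) {
  x <- as.matrix(x); y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  variance * exp(-d2 / (2 * lengthscale^2))
}

# Deterministic farthest-point sampling, independent of sample ordering:
# starts from the largest-norm point (ties: lowest index). The seed is part
# of the signature for API stability; the selection itself is fully
# deterministic.
.farthest_point_sample <- function(x, m, seed) {
  n <- nrow(x)
  if (m == n) return(seq_len(n))
  start <- which.max(rowSums(x^2))
  chosen <- integer(m)
  chosen[1] <- start
  mind <- rowSums(sweep(x, 2, x[start, ])^2)
  for (k in seq_len(m - 1L)) {
    nxt <- which.max(mind)
    chosen[k + 1L] <- nxt
    mind <- pmin(mind, rowSums(sweep(x, 2, x[nxt, ])^2))
  }
  chosen
}

#' Predict with a sparse GPR model
#' @param object a `sparse_gpr` model.
#' @param features numeric matrix (or vector for a single query).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.sparse_gpr <- function(object, features, ...) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  k <- .rbf_kernel(as.matrix(features), object$inducing_points,
                   object$kernel_lengthscale, object$kernel_variance)
  as.numeric(object$prior_mean + k %*% object$weights)
}

#' @export
print.sparse_gpr <- function(x, ...) {
  cat("sparse_gpr:", nrow(x$inducing_points), "inducing points,",
      "lengthscale", format(x$kernel_lengthscale), "\n")
  invisible(x)
}

#' Fit one sparse GPR model per chemical element
#'
#' Atoms of different elements have systematically different property scales
#' (charges, widths, volumes), so one independent model is trained per
#' element, all sharing one descriptor setting.
#'
#' @param features per-atom feature matrix (rows pooled over frames).
#' @param targets per-atom property values.
#' @param elements per-atom element symbols aligned with rows.
#' @param ... passed to [fit_sparse_gpr()] (`n_inducing` may be a single
#'   number, capped at the per-element sample count).
#' @param n_inducing inducing points per element model.
#' @param seed integer seed.
#' @return an object of class `per_element_gpr`.
#' @export
fit_per_element_gpr <- function(features, targets, elements,
                                n_inducing = 32L, seed = 1L, ...) {
  features <- as.matrix(features)
  elements <- as.character(elements)
  models <- list()
  for (z in unique(elements)) {
    sel <- elements == z
    models[[z]] <- fit_sparse_gpr(features[sel, , drop = FALSE],
                                  targets[sel],
                                  n_inducing = min(n_inducing, sum(sel)),
                                  seed = seed, ...)
  }
  structure(list(models = models), class = "per_element_gpr")
}

#' @export
predict.per_element_gpr <- function(object, features, elements, ...) {
  features <- as.matrix(features)
  out <- numeric(nrow(features))
  for (z in unique(elements)) {
    m <- object$models[[z]]
    if (is.null(m)) stop("no model for element ", z, call. = FALSE)
    sel <- elements == z
    out[sel] <- predict(m, features[sel, , drop = FALSE])
  }
  out
}
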