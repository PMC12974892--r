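#' Define a scalar reaction coordinate over labelled atom pairs
#'
#' Two kinds are supported: `"weighted_distance_sum"`, a weighted sum of
#' interatomic distances (e.g. `0.3 d(C10-C15) + 0.7 d(C13-C14)` for an
#' asynchronous Diels-Alder addition), and `"distance_difference"`, the
#' breaking-bond length minus the forming-bond length (weights +1 and -1),
#' as used for the chorismate to prephenate rearrangement.
#'
#' @param kind `"weighted_distance_sum"` or `"distance_difference"`.
#' @param pairs list of length-2 character vectors of atom labels.
#' @param weights numeric coefficients, one per pair. For
#'   `"distance_difference"` these must be `c(1, -1)` (the default).
#' @return an object of class `reaction_coordinate`.
#' @examples
#' rc <- reaction_coordinate("weighted_distance_sum",
#'                           list(c("C10", "C15"), c("C13", "C14")),
#'                           c(0.3, 0.7))
#' @export
reaction_coordinate <- function(kind = c("weighted_distance_sum",
                                         "distance_difference"),
                                pairs, weights = NULL) {
  kind <- match.arg(kind)
  if (!is.list(pairs) || !all(vapply(pairs, length, integer(1)) == 2L)) {
    stop("pairs must be a list of length-2 label vectors", call. = FALSE)
  }
  if (kind == "distance_difference") {
    if (length(pairs) != 2L) {
      stop("distance_difference needs exactly two pairs (breaking, forming)",
           call. = FALSE)
    }
    if (is.null(weights)) weights <- c(1, -1)
    if (!isTRUE(all.equal(sort(weights), c(-1, 1)))) {
      stop("distance_difference weights must be +1 and -1", call. = FALSE)
    }
  }
  if (is.null(weights)) stop("weights are required", call. = FALSE)
  if (length(weights) != length(pairs)) {
    stop("weights and pairs must have equal length", call. = FALSE)
  }
  structure(list(kind = kind, pairs = pairs, weights = as.numeric(weights)),
            class = "reaction_coordinate")
}

#' @export
print.reaction_coordinate <- function(x, ...) {
  terms <- mapply(function(w, p) sprintf("%+g d(%s-%s)", w, p[1], p[2]),
                  x$weights, x$pairs)
  cat("reaction_coordinate [", x$kind, "]: ", paste(terms, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

#' Evaluate a reaction coordinate and its gradient
#'
#' Returns `sum_k w_k d(pair_k)` in angstrom. The gradient with respect to
#' all region coordinates (angstrom^-0, i.e. dimensionless per angstrom
#' displacement) is available via `gradient = TRUE`.
#'
#' @param rc a [reaction_coordinate()].
#' @param region an [ml_region()]; all labels must resolve.
#' @param gradient if `TRUE`, also return the analytic gradient matrix.
#' @return the RC value (numeric), or a list `(value, gradient)` when
#'   `gradient = TRUE`.
#' @export
evaluate_rc <- function(rc, region, gradient = FALSE) {
  stopifnot(inherits(rc, "reaction_coordinate"), inherits(region, "ml_region"))
  coords <- region$coordinates
  value <- 0
  grad <- if (gradient) matrix(0, nrow(coords), 3) else NULL
  for (k in seq_along(rc$pairs)) {
    idx <- .resolve_labels(region, rc$pairs[[k]])
    dvec <- coords[idx[1], ] - coords[idx[2], ]
    d <- sqrt(sum(dvec^2))
    if (d == 0) stop("coincident atoms in RC pair ",
                     paste(rc$pairs[[k]], collapse = "-"), call. = FALSE)
    value <- value + rc$weights[k] * d
    if (gradient) {
      g <- rc$weights[k] * dvec / d
      grad[idx[1], ] <- grad[idx[1], ] + g
      grad[idx[2], ] <- grad[idx[2], ] - g
    }
  }
  if (gradient) list(value = value, gradient = grad) else value
}
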