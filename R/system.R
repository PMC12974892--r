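#' Create an ML region (the reactive subsystem)
#'
#' The ML region is the set of atoms treated by the machine-learned potential
#' and the embedding model. Coordinates are in angstrom at this interface;
#' internal routines convert to bohr as needed.
#'
#' @param elements character vector of element symbols (e.g. `"C"`).
#' @param coordinates numeric n x 3 matrix of positions (angstrom).
#' @param total_charge integer total charge in elementary units.
#' @param atom_labels optional unique per-atom names (e.g. `"C10"`) used by
#'   reaction coordinates. Defaults to element symbol plus 1-based index.
#' @return an object of class `ml_region`.
#' @examples
#' ml_region(c("O", "H", "H"),
#'           rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
#' @export
ml_region <- function(elements, coordinates, total_charge = 0L,
                      atom_labels = NULL) {
  elements <- as.character(elements)
  coordinates <- as.matrix(coordinates)
  storage.mode(coordinates) <- "double"
  if (!is.matrix(coordinates) || ncol(coordinates) != 3) {
    stop("coordinates must be an n x 3 matrix", call. = FALSE)
  }
  if (nrow(coordinates) != length(elements)) {
    stop("coordinate rows (", nrow(coordinates), ") do not match element count (",
         length(elements), ")", call. = FALSE)
  }
  if (abs(total_charge - round(total_charge)) > 1e-9) {
    stop("total_charge must be an integer", call. = FALSE)
  }
  if (is.null(atom_labels)) {
    atom_labels <- paste0(elements, seq_along(elements))
  }
  atom_labels <- as.character(atom_labels)
  if (length(atom_labels) != length(elements)) {
    stop("atom_labels length must match element count", call. = FALSE)
  }
  if (anyDuplicated(atom_labels)) {
    stop("atom_labels must be unique; duplicated: ",
         paste(unique(atom_labels[duplicated(atom_labels)]), collapse = ", "),
         call. = FALSE)
  }
  structure(list(elements = elements,
                 coordinates = coordinates,
                 total_charge = as.integer(round(total_charge)),
                 atom_labels = atom_labels),
            class = "ml_region")
}

#' @export
print.ml_region <- function(x, ...) {
  cat("ml_region:", length(x$elements), "atoms, total charge",
      x$total_charge, "\n")
  cat("  composition:", paste(names(table(x$elements)),
                              table(x$elements), collapse = " "), "\n")
  invisible(x)
}

#' Number of atoms in a region or environment
#' @param x an `ml_region` or `mm_environment`.
#' @return integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "ml_region")) length(x$elements) else nrow(x$positions)
}

#' Create an MM environment of fixed point charges
#'
#' The environment enters the embedding energy only through atom positions,
#' fixed partial charges, and (for the van-der-Waals term) Lennard-Jones
#' parameters.
#'
#' @param positions numeric n x 3 matrix (angstrom).
#' @param charges per-atom partial charges (elementary units).
#' @param lj_sigma,lj_epsilon per-atom Lennard-Jones parameters (angstrom,
#'   kcal/mol); default zero (no van-der-Waals interaction).
#' @return an object of class `mm_environment`.
#' @export
mm_environment <- function(positions, charges,
                           lj_sigma = NULL, lj_epsilon = NULL) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must be n x 3", call. = FALSE)
  n <- nrow(positions)
  charges <- as.numeric(charges)
  if (length(charges) != n) {
    stop("charges length (", length(charges), ") does not match atom count (",
         n, ")", call. = FALSE)
  }
  if (!all(is.finite(charges))) stop("charges must be finite", call. = FALSE)
  if (is.null(lj_sigma)) lj_sigma <- numeric(n)
  if (is.null(lj_epsilon)) lj_epsilon <- numeric(n)
  if (length(lj_sigma) != n || length(lj_epsilon) != n) {
    stop("Lennard-Jones parameter arrays must match atom count", call. = FALSE)
  }
  structure(list(positions = positions, charges = charges,
                 lj_sigma = as.numeric(lj_sigma),
                 lj_epsilon = as.numeric(lj_epsilon)),
            class = "mm_environment")
}

#' @export
print.mm_environment <- function(x, ...) {
  cat("mm_environment:", nrow(x$positions), "point charges, net charge",
      format(sum(x$charges), digits = 6), "e\n")
  invisible(x)
}

#' Bundle the four EMLE energy components
#'
#' The ML/MM energy is decomposed as
#' `E_total = E_gas + E_static + E_induced + E_MM`. The constructor enforces
#' the decomposition identity.
#'
#' @param e_gas,e_static,e_induced,e_mm component energies (kcal/mol).
#' @param forces_ml,forces_mm optional per-atom force matrices (kcal/mol/A).
#' @return an object of class `energy_decomposition` with an `e_total` field.
#' @export
energy_decomposition <- function(e_gas, e_static, e_induced, e_mm,
                                 forces_ml = NULL, forces_mm = NULL) {
  comps <- c(e_gas, e_static, e_induced, e_mm)
  if (!all(is.finite(comps))) stop("energy components must be finite", call. = FALSE)
  e_total <- e_gas + e_static + e_induced + e_mm
  structure(list(e_gas = e_gas, e_static = e_static, e_induced = e_induced,
                 e_mm = e_mm, e_total = e_total,
                 forces_ml = forces_ml, forces_mm = forces_mm),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("energy_decomposition (kcal/mol):\n"))
  cat(sprintf("  gas     %14.6f\n  static  %14.6f\n  induced %14.6f\n  mm      %14.6f\n  total   %14.6f\n",
              x$e_gas, x$e_static, x$e_induced, x$e_mm, x$e_total))
  invisible(x)
}

.resolve_labels <- function(region, labels) {
  idx <- match(labels, region$atom_labels)
  if (anyNA(idx)) {
    stop("unresolved atom label(s): ",
         paste(labels[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  idx
}

#' Read an XYZ file (optionally multi-frame, optionally with charges)
#'
#' Standard XYZ: atom count line, comment line, then `element x y z` rows
#' (angstrom). The point-charge dialect adds a per-atom charge column and
#' optional Lennard-Jones columns: `element x y z charge [sigma epsilon]`.
#' Atom labels may be supplied in the comment line as `labels=C10,O2,...`.
#'
#' @param path file path.
#' @return a list of frames; each frame is a list with `elements`,
#'   `coordinates`, `comment`, and when present `charges`, `lj_sigma`,
#'   `lj_epsilon`, `labels`.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0L))]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ: expected atom count at line ", i, call. = FALSE)
    comment <- if (i + 1L <= length(lines)) lines[i + 1L] else ""
    rows <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(rows), "\\s+")
    ncol_row <- unique(vapply(toks, length, integer(1)))
    if (length(ncol_row) != 1L) stop("inconsistent column counts in XYZ frame", call. = FALSE)
    el <- vapply(toks, `[[`, character(1), 1L)
    num <- t(vapply(toks, function(tk) as.numeric(tk[-1L]), numeric(ncol_row - 1L)))
    frame <- list(elements = el, coordinates = num[, 1:3, drop = FALSE],
                  comment = comment)
    if (ncol_row >= 5L) frame$charges <- num[, 4L]
    if (ncol_row >= 7L) {
      frame$lj_sigma <- num[, 5L]
      frame$lj_epsilon <- num[, 6L]
    }
    m <- regmatches(comment, regexpr("labels=[^ ]+", comment))
    if (length(m) == 1L && nzchar(m)) {
      frame$labels <- strsplit(sub("^labels=", "", m), ",")[[1]]
    }
    frames[[length(frames) + 1L]] <- frame
    i <- i + 2L + n
  }
  frames
}

#' Write frames to an XYZ file
#'
#' @param frames a single frame (list with `elements`, `coordinates`, ...) or
#'   a list of frames as returned by [read_xyz()]; `ml_region` objects are
#'   accepted and carry their labels into the comment line.
#' @param path output path.
#' @export
write_xyz <- function(frames, path) {
  if (inherits(frames, "ml_region")) {
    frames <- list(list(elements = frames$elements,
                        coordinates = frames$coordinates,
                        labels = frames$atom_labels))
  }
  if (!is.null(frames$elements)) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- length(fr$elements)
    comment <- fr$comment %||% ""
    if (!is.null(fr$labels) && !grepl("labels=", comment)) {
      comment <- trimws(paste(comment,
                              paste0("labels=", paste(fr$labels, collapse = ","))))
    }
    writeLines(as.character(n), con)
    writeLines(comment, con)
    for (k in seq_len(n)) {
      row <- sprintf("%-3s %16.10f %16.10f %16.10f", fr$elements[k],
                     fr$coordinates[k, 1], fr$coordinates[k, 2],
                     fr$coordinates[k, 3])
      if (!is.null(fr$charges)) {
        row <- paste0(row, sprintf(" %14.10f", fr$charges[k]))
        if (!is.null(fr$lj_sigma)) {
          row <- paste0(row, sprintf(" %12.8f %12.8f",
                                     fr$lj_sigma[k], fr$lj_epsilon[k]))
        }
      }
      writeLines(row, con)
    }
  }
  invisible(path)
}

#' Convert an XYZ frame to an `ml_region`
#' @param frame one frame from [read_xyz()].
#' @param total_charge total charge of the region.
#' @return an `ml_region`.
#' @export
frame_to_region <- function(frame, total_charge = 0L) {
  ml_region(frame$elements, frame$coordinates, total_charge,
            atom_labels = frame$labels)
}

#' Convert a point-charge XYZ frame to an `mm_environment`
#' @param frame one frame from [read_xyz()]; must carry a charge column.
#' @return an `mm_environment`.
#' @export
frame_to_environment <- function(frame) {
  if (is.null(frame$charges)) {
    stop("frame has no charge column; expected the point-charge XYZ dialect",
         call. = FALSE)
  }
  mm_environment(frame$coordinates, frame$charges,
                 frame$lj_sigma, frame$lj_epsilon)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.pair_distance <- function(coords, i, j) {
  sqrt(sum((coords[i, ] - coords[j, ])^2))
}
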