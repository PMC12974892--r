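#' Save trained embedding models to a JSON archive
#'
#' The archive is a single JSON container of named arrays plus a metadata
#' block (descriptor settings, element vocabulary, hyperparameters, format
#' version), covering the static model (electronegativity/width/volume
#' GPRs) and the polarizability model (per-element `k_Z`, optional flexible
#' `k_alpha` GPR, damping constant).
#'
#' @param path output file path.
#' @param static a [static_model()] or `NULL`.
#' @param pol a [polarizability_model()] or `NULL`.
#' @return `path`, invisibly.
#' @export
save_emle_model <- function(path, static = NULL, pol = NULL) {
  ser_gpr <- function(m) {
    if (is.null(m)) return(NULL)
    list(inducing_points = unclass(m$inducing_points),
         weights = m$weights,
         kernel_lengthscale = m$kernel_lengthscale,
         kernel_variance = m$kernel_variance,
         noise_variance = m$noise_variance,
         prior_mean = m$prior_mean)
  }
  ser_pel <- function(m) {
    if (is.null(m)) return(NULL)
    lapply(m$models, ser_gpr)
  }
  settings <- if (!is.null(static)) static$settings else pol$settings
  obj <- list(
    format = "emler-model",
    version = 1L,
    descriptor_settings = if (!is.null(settings)) unclass(settings),
    static = if (!is.null(static)) list(
      electronegativity = ser_pel(static$electronegativity_model),
      width = ser_pel(static$width_model),
      volume = ser_pel(static$volume_model),
      hardness_rule = static$hardness_rule
    ),
    polarizability = if (!is.null(pol)) list(
      k_z = as.list(pol$k_z),
      mode = pol$mode,
      thole_damping_a = pol$thole_damping_a,
      k_alpha = ser_gpr(pol$k_alpha_model)
    )
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = FALSE)
  invisible(path)
}

#' Load an embedding-model archive
#'
#' @param path archive written by [save_emle_model()].
#' @return list with `static` ([static_model()] or NULL), `pol`
#'   ([polarizability_model()] or NULL), and `settings`.
#' @export
load_emle_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "emler-model")) {
    stop("not an emler model archive: ", path, call. = FALSE)
  }
  settings <- NULL
  if (!is.null(obj$descriptor_settings)) {
    ds <- obj$descriptor_settings
    settings <- descriptor_settings(ds$cutoff_radius, ds$n_radial,
                                    ds$gaussian_width, ds$element_vocabulary)
  }
  de_gpr <- function(x) {
    if (is.null(x)) return(NULL)
    structure(list(inducing_points = as.matrix(x$inducing_points),
                   weights = as.numeric(x$weights),
                   kernel_lengthscale = x$kernel_lengthscale,
                   kernel_variance = x$kernel_variance,
                   noise_variance = x$noise_variance,
                   prior_mean = x$prior_mean),
              class = "sparse_gpr")
  }
  de_pel <- function(x) {
    if (is.null(x)) return(NULL)
    structure(list(models = lapply(x, de_gpr)), class = "per_element_gpr")
  }
  static <- NULL
  if (!is.null(obj$static)) {
    static <- static_model(de_pel(obj$static$electronegativity),
                           de_pel(obj$static$width),
                           de_pel(obj$static$volume),
                           settings, obj$static$hardness_rule)
  }
  pol <- NULL
  if (!is.null(obj$polarizability)) {
    p <- obj$polarizability
    pol <- polarizability_model(unlist(p$k_z), p$mode,
                                k_alpha_model = de_gpr(p$k_alpha),
                                settings = settings,
                                thole_damping_a = p$thole_damping_a)
  }
  list(static = static, pol = pol, settings = settings)
}

#' Read a YAML run configuration
#'
#' Thin wrapper over [yaml::read_yaml()]; run configs list system files,
#' model archive paths, the embedding variant, restraints, integrator
#' settings and the seed. Used by the command-line interface.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
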