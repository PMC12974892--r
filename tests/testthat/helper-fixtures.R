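# Shared, lazily built fixtures. Everything is generated in code from fixed
# seeds; expensive objects (the calibrated surface, trained models) are
# cached for the whole test session.

.fx <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_gt <- function() fx("gt", function() ground_truth_model())

fx_settings <- function() {
  fx("settings", function() {
    descriptor_settings(element_vocabulary = c("H", "C", "O"))
  })
}

fx_train_conformers <- function() {
  fx("train_conf", function() generate_conformers(fx_gt(), 60, seed = 11))
}

fx_test_conformers <- function() {
  fx("test_conf", function() generate_conformers(fx_gt(), 15, seed = 99))
}

fx_static_model <- function() {
  fx("static_model", function() {
    gt <- fx_gt()
    train <- fx_train_conformers()
    tab <- emit_reference_tables(gt, train)
    fit_static_model(train, tab$properties, fx_settings(),
                     n_inducing = 60, lengthscale = 1)
  })
}

fx_ref_tensors <- function(mode = "flexible") {
  fx(paste0("tensors_", mode), function() {
    gt <- fx_gt()
    tab <- emit_reference_tables(gt, fx_train_conformers(),
                                 polarizability_mode = mode)
    lapply(seq_len(nrow(tab$polarizabilities)), function(i) {
      r <- tab$polarizabilities[i, ]
      matrix(c(r$xx, r$xy, r$xz, r$xy, r$yy, r$yz, r$xz, r$yz, r$zz), 3, 3)
    })
  })
}

fx_volumes <- function() {
  fx("volumes", function() {
    gt <- fx_gt()
    lapply(fx_train_conformers(), function(r) gt_properties(gt, r)$v)
  })
}

fx_flexible_model <- function() {
  fx("flexible_model", function() {
    gt <- fx_gt()
    fit_flexible_alpha(fx_ref_tensors("flexible"), fx_train_conformers(),
                       fx_volumes(), gt$k_z, fx_settings(), lambda = 1e-6,
                       n_inducing = 60, damping_a = gt$thole_damping_a,
                       seed = 3)
  })
}

# A small random ML region + MM environment pair for electrostatics tests.
random_system <- function(seed, n_ml = 4, n_mm = 6) {
  set.seed(seed)
  elements <- sample(c("H", "C", "O"), n_ml, replace = TRUE)
  region <- ml_region(elements, matrix(stats::rnorm(n_ml * 3, sd = 1.5),
                                       n_ml, 3) + 5)
  env <- mm_environment(matrix(stats::rnorm(n_mm * 3, sd = 2), n_mm, 3) - 5,
                        stats::runif(n_mm, -0.5, 0.5))
  list(region = region, env = env)
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
}

rotate_region <- function(region, rot, shift = c(0, 0, 0)) {
  region$coordinates <- region$coordinates %*% t(rot) +
    matrix(shift, nrow(region$coordinates), 3, byrow = TRUE)
  region
}

rotate_env <- function(env, rot, shift = c(0, 0, 0)) {
  env$positions <- env$positions %*% t(rot) +
    matrix(shift, nrow(env$positions), 3, byrow = TRUE)
  env
}

# 1D particle-on-a-line fixtures: one mobile atom tethered to a fixed
# anchor; the RC is the anchor-particle distance, and the y/z motion of the
# particle is confined so the distance is effectively |x|.
.line_system <- function(u_fun, du_fun) {
  anchor_k <- 500
  ff <- function(region) {
    x <- region$coordinates[2, 1]
    f <- matrix(0, 2, 3)
    f[2, 1] <- -du_fun(x)
    f[2, 2:3] <- -2 * anchor_k * region$coordinates[2, 2:3]
    list(energy = u_fun(x) + anchor_k * sum(region$coordinates[2, 2:3]^2),
         forces = f)
  }
  rc <- reaction_coordinate("weighted_distance_sum", list(c("X1", "P2")), 1)
  init <- function(center) {
    ml_region(c("C", "C"), rbind(c(0, 0, 0), c(center, 0, 0)),
              atom_labels = c("X1", "P2"))
  }
  list(ff = ff, rc = rc, init = init,
       masses = c(1e9, 12.011))   # anchor effectively immobile
}

.sample_line <- function(sys, windows, steps, seed, replicas = 1) {
  run_umbrella(windows, sys$ff, sys$init, sys$rc, replicas = replicas,
               steps_per_window = steps, equilibration_steps = 200,
               dt_fs = 1.0, temperature = 300, friction_fs = 0.05,
               sample_stride = 4, masses = sys$masses, seed = seed)
}
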