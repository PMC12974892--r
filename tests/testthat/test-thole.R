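test_that("fixed-mode polarizabilities are k_Z times volume", {
  reg <- ml_region("C", matrix(0, 1, 3))
  dens <- density_parameters(0, 0.5, 4, 2.0)
  model <- polarizability_model(c(C = 1.0), "fixed")
  expect_identical(atomic_polarizabilities(model, dens, reg), 2.0)
  expect_error(atomic_polarizabilities(polarizability_model(c(O = 1), "fixed"),
                                       dens, reg), "missing from k_Z")
})

test_that("flexible mode with unit correction equals fixed mode bitwise", {
  settings <- fx_settings()
  reg <- fx_test_conformers()[[1]]
  dens <- predict_density(fx_gt(), reg)
  kz <- c(H = 0.4, C = 0.6, O = 0.5)
  unit_ka <- structure(list(inducing_points = matrix(0, 1, 3 * 16),
                            weights = 0, kernel_lengthscale = 1,
                            kernel_variance = 1, noise_variance = 0,
                            prior_mean = 1),
                       class = "sparse_gpr")
  fixed <- polarizability_model(kz, "fixed")
  flex <- polarizability_model(kz, "flexible", k_alpha_model = unit_ka,
                               settings = settings)
  expect_identical(atomic_polarizabilities(flex, dens, reg),
                   atomic_polarizabilities(fixed, dens, reg))
})

test_that("induction closed forms: zero field, single atom, two-atom chain", {
  reg1 <- ml_region("O", matrix(0, 1, 3))
  env0 <- mm_environment(matrix(c(8, 0, 0), 1, 3), 0)
  out0 <- solve_induction(2.5, reg1, env0)
  expect_equal(out0$induced_dipoles, matrix(0, 1, 3))
  expect_identical(out0$e_induced, 0)
  # uniform field on one atom: mu = alpha E, E_ind = -alpha E^2 / 2
  e0 <- 0.013
  out1 <- solve_induction(2.5, reg1, field = matrix(c(e0, 0, 0), 1, 3))
  expect_equal(out1$induced_dipoles[1, 1], 2.5 * e0, tolerance = 1e-12)
  expect_equal(out1$e_induced, -0.5 * 2.5 * e0^2, tolerance = 1e-12)
  # two-atom chain along the field, no damping: closed-form alpha_parallel
  a1 <- 3; a2 <- 5; d <- 4  # bohr
  reg2 <- ml_region(c("C", "C"),
                    rbind(c(0, 0, 0), c(d * 0.52917721092, 0, 0)))
  mp <- molecular_polarizability(c(a1, a2), reg2, damping_a = 1e7)
  closed <- (a1 + a2 + 4 * a1 * a2 / d^3) / (1 - 4 * a1 * a2 / d^6)
  expect_equal(mp$tensor[1, 1], closed, tolerance = 1e-8)
})

test_that("direct and Jacobi induction solvers agree", {
  for (seed in 1:3) {
    sys <- random_system(seed)
    alphas <- runif(4, 1, 6)
    d <- solve_induction(alphas, sys$region, sys$env, solver = "direct")
    j <- solve_induction(alphas, sys$region, sys$env, solver = "jacobi")
    expect_lt(max(abs(d$induced_dipoles - j$induced_dipoles)), 1e-8)
    expect_equal(d$e_induced, j$e_induced, tolerance = 1e-8)
  }
})

test_that("induced energy is never positive and dipoles rotate equivariantly", {
  for (seed in 1:6) {
    sys <- random_system(seed)
    alphas <- runif(4, 1, 8)
    out <- solve_induction(alphas, sys$region, sys$env)
    expect_lte(out$e_induced, 0)
    rot <- random_rotation(seed + 50)
    shift <- rnorm(3)
    out_r <- solve_induction(alphas, rotate_region(sys$region, rot, shift),
                             rotate_env(sys$env, rot, shift))
    expect_equal(out_r$e_induced, out$e_induced, tolerance = 1e-10)
    expect_equal(out_r$induced_dipoles, out$induced_dipoles %*% t(rot),
                 tolerance = 1e-9)
  }
})

test_that("overpolarizing geometries report the offending pair", {
  reg <- ml_region(c("C", "C"), rbind(c(0, 0, 0), c(0.5, 0, 0)),
                   atom_labels = c("Ca", "Cb"))
  expect_error(solve_induction(c(30, 30), reg, field = matrix(0.01, 2, 3),
                               damping_a = 1e7),
               "Ca-Cb|Cb-Ca")
})

test_that("molecular polarizability: single atom, far limit, finite field", {
  reg1 <- ml_region("O", matrix(0, 1, 3))
  mp1 <- molecular_polarizability(4.2, reg1)
  expect_equal(mp1$tensor, diag(4.2, 3), tolerance = 1e-12)
  # far-apart identical atoms: isotropic value -> sum of alphas
  reg2 <- ml_region(c("C", "C"), rbind(c(0, 0, 0), c(80, 0, 0)))
  mp2 <- molecular_polarizability(c(3, 3), reg2)
  expect_equal(mp2$isotropic, 6, tolerance = 1e-3)
  # three-atom toy vs finite-field numeric differentiation
  reg3 <- ml_region(c("O", "C", "H"),
                    rbind(c(0, 0, 0), c(1.3, 0.2, 0), c(2.0, 1.1, 0.5)))
  alphas <- c(5, 9, 2)
  mp3 <- molecular_polarizability(alphas, reg3, damping_a = 0.39)
  expect_lt(max(abs(mp3$tensor - t(mp3$tensor))), 1e-10)
  num <- matrix(0, 3, 3)
  h <- 1e-4
  for (k in 1:3) {
    ep <- em <- matrix(0, 3, 3)
    ep[, k] <- h; em[, k] <- -h
    mup <- colSums(solve_induction(alphas, reg3, field = ep,
                                   damping_a = 0.39)$induced_dipoles)
    mum <- colSums(solve_induction(alphas, reg3, field = em,
                                   damping_a = 0.39)$induced_dipoles)
    num[, k] <- (mup - mum) / (2 * h)
  }
  expect_lt(max(abs(mp3$tensor - num)), 1e-6)
})

test_that("k_Z fitting recovers the generator exactly and is idempotent", {
  gt <- fx_gt()
  conf <- fx_train_conformers()[seq(1, 60, by = 2)]
  vols <- lapply(conf, function(r) gt_properties(gt, r)$v)
  tens <- lapply(conf, function(r) {
    p <- gt_properties(gt, r)
    molecular_polarizability(unname(gt$k_z[r$elements]) * p$v, r,
                             gt$thole_damping_a)$tensor
  })
  kz <- fit_kz(tens, conf, vols, damping_a = gt$thole_damping_a)
  expect_lt(max(abs(kz[names(gt$k_z)] / gt$k_z - 1)), 1e-3)
  # duplicated conformers: identical fit
  kz2 <- fit_kz(c(tens, tens), c(conf, conf), c(vols, vols),
                damping_a = gt$thole_damping_a)
  expect_equal(kz2, kz, tolerance = 1e-9)
  # single-element single-atom closed form: mean ratio alpha/v
  reg <- ml_region("O", matrix(0, 1, 3))
  kz3 <- fit_kz(list(diag(6, 3), diag(6, 3)), list(reg, reg),
                list(10, 10))
  expect_equal(unname(kz3["O"]), 0.6, tolerance = 1e-6)
})

test_that("flexible correction recovers the ground-truth field", {
  gt <- fx_gt()
  pm <- fx_flexible_model()
  settings <- fx_settings()
  err_ka <- err_alpha <- c()
  for (reg in fx_test_conformers()) {
    p <- gt_properties(gt, reg)
    feat <- compute_descriptors(reg, settings)
    ka <- predict(pm$k_alpha_model, feat)
    err_ka <- c(err_ka, ka / p$k_alpha - 1)
    dens <- density_parameters(p$q, p$s, rep(1, 5), p$v)
    al <- atomic_polarizabilities(pm, dens, reg)
    err_alpha <- c(err_alpha, al / p$alphas - 1)
  }
  expect_lt(sqrt(mean(err_ka^2)), 0.05)
  expect_lt(sqrt(mean(err_alpha^2)), 0.02)
})

test_that("regularization limits: infinite lambda fixed, small lambda nested", {
  gt <- fx_gt()
  conf <- fx_train_conformers()[seq(1, 60, by = 3)]
  vols <- lapply(conf, function(r) gt_properties(gt, r)$v)
  tens <- lapply(conf, function(r) {
    p <- gt_properties(gt, r)
    molecular_polarizability(p$alphas, r, gt$thole_damping_a)$tensor
  })
  inf_model <- fit_flexible_alpha(tens, conf, vols, gt$k_z, fx_settings(),
                                  lambda = 1e12, n_inducing = 20,
                                  damping_a = gt$thole_damping_a)
  feat <- compute_descriptors(conf[[1]], fx_settings())
  expect_equal(predict(inf_model$k_alpha_model, feat), rep(1, 5),
               tolerance = 1e-6)
  # lambda = 0 on noise-free data: training misfit below the fixed model
  zero_model <- fit_flexible_alpha(tens, conf, vols, gt$k_z, fx_settings(),
                                   lambda = 0, n_inducing = 40,
                                   damping_a = gt$thole_damping_a)
  misfit <- function(pmod) {
    tot <- 0
    for (i in seq_along(conf)) {
      p <- gt_properties(gt, conf[[i]])
      dens <- density_parameters(p$q, p$s, rep(1, 5), p$v)
      al <- atomic_polarizabilities(pmod, dens, conf[[i]])
      tot <- tot + sum((molecular_polarizability(al, conf[[i]],
                                                 gt$thole_damping_a)$tensor -
                          tens[[i]])^2)
    }
    tot
  }
  fixed_model <- polarizability_model(gt$k_z, "fixed",
                                      thole_damping_a = gt$thole_damping_a)
  expect_lt(misfit(zero_model), misfit(fixed_model))
})
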