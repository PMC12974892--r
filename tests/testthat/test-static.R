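test_that("the Slater-atom potential matches radial quadrature", {
  # valence cloud alone (q = 0 part): s = 1 bohr, d = 2 bohr
  v_full <- slater_potential(q = 0, n_val = 1, s = 1, d = 2)
  cloud <- v_full - 1 / 2           # remove the +N/d core part
  expect_equal(abs(cloud), 0.364665, tolerance = 1e-6)
  # radial-quadrature oracle for several (s, d)
  for (case in list(c(1, 2), c(0.5, 1.3), c(0.8, 4))) {
    s <- case[1]; d <- case[2]
    rho <- function(r) exp(-r / s) / (8 * pi * s^3)
    inner <- stats::integrate(function(r) rho(r) * 4 * pi * r^2, 0, d,
                              rel.tol = 1e-12)$value
    outer_ <- stats::integrate(function(r) rho(r) * 4 * pi * r, d, Inf,
                               rel.tol = 1e-12)$value
    v_quad <- 1 / d - (inner / d + outer_)   # core + cloud, neutral atom
    expect_equal(slater_potential(0, 1, s, d), v_quad, tolerance = 1e-8)
  }
})

test_that("Slater potential limits: asymptotic point charge, penetration sign", {
  s <- 0.7; q <- -0.3; n <- 6
  d <- 30 * s
  expect_lt(abs(slater_potential(q, n, s, d) - q / d), 1e-10 * (abs(q / d) + 1))
  # neutral atom: positive potential at any finite distance
  for (d in c(0.1, 1, 5, 10)) {
    expect_gt(slater_potential(0, 4, 0.6, d), 0)
  }
  expect_error(slater_potential(0, 1, 1, 0), "self-interaction")
})

test_that("electronegativity equalization handles the documented cases", {
  # single atom: charge equals the constraint
  expect_equal(eeq_charges(0.2, 0.8, matrix(0, 1, 3), -2)$charges, -2)
  # homonuclear diatomic, total charge -2: symmetric split
  co <- rbind(c(0, 0, 0), c(2.5, 0, 0))
  q <- eeq_charges(c(0.3, 0.3), c(0.9, 0.9), co, -2)$charges
  expect_equal(q, c(-1, -1), tolerance = 1e-12)
  # heteronuclear pair vs hand-solved 3x3 system
  chi <- c(0.1, 0.4); eta <- c(0.8, 1.1); d <- 3
  co <- rbind(c(0, 0, 0), c(d, 0, 0))
  a <- rbind(c(eta[1], 1 / d, 1), c(1 / d, eta[2], 1), c(1, 1, 0))
  hand <- solve(a, c(-chi, 0))
  q <- eeq_charges(chi, eta, co, 0)$charges
  expect_equal(q, hand[1:2], tolerance = 1e-12)
  expect_gt(q[1], 0)  # lower electronegativity donates
  expect_lt(q[2], 0)
})

test_that("predicted densities conserve total charge across conformers", {
  sm <- fx_static_model()
  for (reg in fx_test_conformers()[1:8]) {
    dens <- predict_density(sm, reg)
    expect_lt(abs(sum(dens$charges) - reg$total_charge), 1e-10)
    expect_true(all(dens$widths > 0))
    expect_true(all(dens$volumes > 0))
  }
})

test_that("static energy: zero charges, point-charge limit, brute force", {
  reg <- ml_region("O", matrix(0, 1, 3))
  dens <- density_parameters(1, 0.5, 6, 20)
  env0 <- mm_environment(matrix(c(5, 0, 0), 1, 3), 0)
  expect_identical(static_energy(dens, reg, env0), 0)
  # single unit charges at 10 A: Coulomb 1/d in a.u.
  env <- mm_environment(matrix(c(10, 0, 0), 1, 3), 1)
  d_bohr <- 10 / 0.52917721092
  expect_equal(static_energy(dens, reg, env), 1 / d_bohr, tolerance = 1e-8)
  # brute-force pairwise oracle on random systems
  for (seed in 1:5) {
    sys <- random_system(seed)
    dens <- density_parameters(runif(4, -0.5, 0.5), runif(4, 0.3, 0.8),
                               c(1, 4, 6, 6)[1:4], runif(4, 5, 30))
    e <- static_energy(dens, sys$region, sys$env)
    brute <- 0
    for (i in 1:4) for (j in seq_len(nrow(sys$env$positions))) {
      d <- sqrt(sum((sys$region$coordinates[i, ] -
                       sys$env$positions[j, ])^2)) / 0.52917721092
      brute <- brute + sys$env$charges[j] *
        slater_potential(dens$charges[i], dens$valence_populations[i],
                         dens$widths[i], d)
    }
    expect_equal(e, brute, tolerance = 1e-10)
  }
  expect_error(static_energy(dens, sys$region,
                             mm_environment(sys$region$coordinates,
                                            rep(0.1, 4))),
               "overlapping")
})

test_that("static forces match finite differences and obey Newton's third law", {
  for (seed in 1:3) {
    sys <- random_system(seed)
    dens <- density_parameters(runif(4, -0.5, 0.5), runif(4, 0.3, 0.8),
                               rep(4, 4), runif(4, 5, 30))
    out <- static_energy(dens, sys$region, sys$env, gradient = TRUE)
    fd <- matrix(0, 4, 3)
    h <- 1e-4 * 0.52917721092   # 1e-4 bohr step in angstrom
    for (i in 1:4) for (k in 1:3) {
      rp <- sys$region; rp$coordinates[i, k] <- rp$coordinates[i, k] + h
      rm <- sys$region; rm$coordinates[i, k] <- rm$coordinates[i, k] - h
      fd[i, k] <- (static_energy(dens, rp, sys$env) -
                     static_energy(dens, rm, sys$env)) / (2 * h / 0.52917721092)
    }
    expect_lt(max(abs(-out$forces_ml - fd)) / max(abs(fd)), 1e-6)
    expect_lt(max(abs(colSums(out$forces_ml) + colSums(out$forces_mm))),
              1e-10)
  }
})

test_that("MM embedding is plain Coulomb and the Slater small-width limit", {
  # 2x2 hand-computed Coulomb sum
  reg <- ml_region(c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)))
  env <- mm_environment(rbind(c(0, 3, 0), c(4, 0, 0)), c(0.5, -0.25))
  qml <- c(0.2, -0.6)
  b <- 0.52917721092
  hand <- 0.2 * 0.5 / (3 / b) + 0.2 * (-0.25) / (4 / b) +
    (-0.6) * 0.5 / (sqrt(10) / b) + (-0.6) * (-0.25) / (3 / b)
  expect_equal(mm_embedding_energy(qml, reg, env), hand, tolerance = 1e-12)
  expect_identical(mm_embedding_energy(c(0, 0), reg, env), 0)
  # s -> 0+, N -> 0 limit of the Slater model is the point-charge Coulomb
  dens <- density_parameters(qml, c(1e-3, 1e-3), c(0, 0), c(1, 1))
  expect_equal(static_energy(dens, reg, env),
               mm_embedding_energy(qml, reg, env), tolerance = 1e-8)
  # forces match finite differences too
  out <- mm_embedding_energy(qml, reg, env, gradient = TRUE)
  h <- 1e-5
  fd <- matrix(0, 2, 3)
  for (i in 1:2) for (k in 1:3) {
    rp <- reg; rp$coordinates[i, k] <- rp$coordinates[i, k] + h
    rm <- reg; rm$coordinates[i, k] <- rm$coordinates[i, k] - h
    fd[i, k] <- (mm_embedding_energy(qml, rp, env) -
                   mm_embedding_energy(qml, rm, env)) / (2 * h / b)
  }
  expect_lt(max(abs(-out$forces_ml - fd)) / max(abs(fd)), 1e-6)
})

test_that("held-out property recovery meets the generator's targets", {
  gt <- fx_gt()
  sm <- fx_static_model()
  err_q <- err_s <- err_v <- c()
  for (reg in fx_test_conformers()) {
    d <- predict_density(sm, reg)
    p <- gt_properties(gt, reg)
    err_q <- c(err_q, d$charges - p$q)
    err_s <- c(err_s, d$widths / p$s - 1)
    err_v <- c(err_v, d$volumes / p$v - 1)
  }
  expect_lt(sqrt(mean(err_q^2)), 0.01)   # charges, e
  expect_lt(sqrt(mean(err_s^2)), 0.01)   # widths, relative
  expect_lt(sqrt(mean(err_v^2)), 0.01)   # volumes, relative
})
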