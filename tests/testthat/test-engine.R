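test_that("gas potentials are gradient-validated at registration", {
  bad <- function(region) {
    d <- sqrt(sum((region$coordinates[1, ] - region$coordinates[2, ])^2))
    list(energy = (d - 1)^2, gradient = matrix(0, 2, 3))  # wrong gradient
  }
  probe <- list(ml_region(c("C", "C"), rbind(c(0, 0, 0), c(1.3, 0, 0))))
  expect_error(gas_phase_potential(bad, "bad", "C", probe = probe),
               "gradient validation")
  good <- function(region) {
    dv <- region$coordinates[1, ] - region$coordinates[2, ]
    d <- sqrt(sum(dv^2))
    g <- 2 * (d - 1) * dv / d
    list(energy = (d - 1)^2, gradient = rbind(g, -g))
  }
  expect_s3_class(gas_phase_potential(good, "bond", "C", probe = probe),
                  "gas_phase_potential")
})

test_that("toy surface calibration hits the requested barrier and asymmetry", {
  surf <- fx_gt()$surface    # barrier 20, asymmetry -3 defaults
  prof <- toy_gas_profile(surf)
  i_r <- which.min(abs(prof$xi - surf$params$rc_reactant))
  i_p <- which.min(abs(prof$xi - surf$params$rc_product))
  barrier <- max(prof$energy[i_r:i_p]) - prof$energy[i_r]
  asym <- prof$energy[i_p] - prof$energy[i_r]
  expect_equal(barrier, 20, tolerance = 0.01)
  expect_equal(asym, -3, tolerance = 0.01)
})

test_that("a symmetric toy surface has a symmetric relaxed profile", {
  surf <- fx("sym_surface", function() {
    toy_reactive_surface(barrier = 15, asymmetry = 0,
                         params = list(r_cc = 1.35, rep_rho = 0.4))
  })
  p <- surf$params
  expect_equal(p$asymmetry, 0, tolerance = 0.01)
  expect_equal(p$rc_product, -p$rc_reactant, tolerance = 0.06)
})

test_that("total energy reduces to the gas term without an environment", {
  gt <- fx_gt()
  reg <- toy_equilibrium_region(gt$surface, "reactant")
  dec <- total_energy(reg, NULL, gt$surface, gt,
                      gt_polarizability_backend(gt))
  expect_identical(dec$e_static, 0)
  expect_identical(dec$e_induced, 0)
  expect_identical(dec$e_mm, 0)
  expect_identical(dec$e_total, dec$e_gas)
})

test_that("variant contract: mechanical drops exactly the induced term", {
  gt <- fx_gt()
  reg <- toy_equilibrium_region(gt$surface, "ts")
  env <- fx("cat_env", function() gt_catalytic_environment(gt, seed = 42))
  pol <- gt_polarizability_backend(gt)
  emle <- total_energy(reg, env, gt$surface, gt, pol,
                       embedding_variant("emle"), ml_lj = gt$ml_lj)
  mech <- total_energy(reg, env, gt$surface, gt, pol,
                       embedding_variant("mechanical"), ml_lj = gt$ml_lj)
  expect_identical(mech$e_gas, emle$e_gas)
  expect_identical(mech$e_static, emle$e_static)
  expect_identical(mech$e_induced, 0)
  expect_lt(emle$e_induced, 0)
  expect_equal(emle$e_total - mech$e_total, emle$e_induced,
               tolerance = 1e-12)
  # mm_fixed validates its charge set length
  expect_error(total_energy(reg, env, gt$surface,
                            variant = embedding_variant("mm_fixed",
                                                        fixed_charges = 1)),
               "does not match")
})

test_that("fast-path total forces match the finite-difference mode", {
  gt <- fx_gt()
  reg <- toy_equilibrium_region(gt$surface, "reactant")
  env <- fx("cat_env", function() gt_catalytic_environment(gt, seed = 42))
  pol <- gt_polarizability_backend(gt)
  qR <- gt_fixed_charges(gt, "reactant")
  # mm_fixed has no parameter response: fast and fd agree to FD accuracy
  var_mm <- embedding_variant("mm_fixed", fixed_charges = qR)
  fast <- total_energy(reg, env, gt$surface, gt, pol, var_mm,
                       ml_lj = gt$ml_lj, force_mode = "fast")
  fd <- total_energy(reg, env, gt$surface, gt, pol, var_mm,
                     ml_lj = gt$ml_lj, force_mode = "fd")
  # agreement is limited by the fd mode's fixed 1e-3 bohr step
  scale <- max(abs(fd$forces_ml))
  expect_lt(max(abs(fast$forces_ml - fd$forces_ml)) / scale, 5e-5)
  expect_lt(max(abs(fast$forces_mm - fd$forces_mm)) / scale, 5e-5)
  # total momentum is conserved in fd mode (parameter response included)
  full <- total_energy(reg, env, gt$surface, gt, pol,
                       embedding_variant("emle"), ml_lj = gt$ml_lj,
                       force_mode = "fd")
  net <- colSums(full$forces_ml) + colSums(full$forces_mm)
  expect_lt(max(abs(net)) / max(abs(full$forces_ml)), 1e-6)
})

test_that("all energy components are invariant under joint rigid motion", {
  gt <- fx_gt()
  reg <- toy_equilibrium_region(gt$surface, "ts")
  env <- fx("cat_env", function() gt_catalytic_environment(gt, seed = 42))
  pol <- gt_polarizability_backend(gt)
  d0 <- total_energy(reg, env, gt$surface, gt, pol,
                     embedding_variant("emle"), ml_lj = gt$ml_lj,
                     force_mode = "fast")
  for (trial in 1:3) {
    rot <- random_rotation(trial + 7)
    shift <- rnorm(3, sd = 2)
    d1 <- total_energy(rotate_region(reg, rot, shift),
                       rotate_env(env, rot, shift),
                       gt$surface, gt, pol, embedding_variant("emle"),
                       ml_lj = gt$ml_lj, force_mode = "fast")
    for (comp in c("e_gas", "e_static", "e_induced", "e_mm", "e_total")) {
      expect_equal(d1[[comp]], d0[[comp]], tolerance = 1e-9)
    }
    # forces rotate equivariantly
    expect_equal(d1$forces_ml, d0$forces_ml %*% t(rot), tolerance = 1e-6)
  }
})

test_that("induced_from_reference implements the difference identity", {
  expect_identical(induced_from_reference(-10, -7, -2), -1)
  expect_identical(induced_from_reference(-9, -7, -2), 0)
  set.seed(5)
  for (i in 1:20) {
    e <- rnorm(3, sd = 20)
    ind <- induced_from_reference(e[1], e[2], e[3])
    expect_lt(abs(ind + e[2] + e[3] - e[1]), 1e-12 * max(abs(e), 1))
  }
})

test_that("restraints follow the no-half engine convention", {
  reg <- ml_region(c("C", "C"), rbind(c(0, 0, 0), c(3.0, 0, 0)),
                   atom_labels = c("C2", "C8"))
  guard <- restraint("one_sided_distance", pair = c("C2", "C8"),
                     force_constant = 100, threshold = 2.7)
  out <- restraint_energy(guard, reg)
  expect_identical(out$energy, 0)
  expect_true(all(out$forces == 0))
  reg$coordinates[2, 1] <- 2.6
  out <- restraint_energy(guard, reg)
  expect_equal(out$energy, 100 * (2.6 - 2.7)^2, tolerance = 1e-12)  # 1.0
  expect_equal(out$energy, 1.0, tolerance = 1e-12)
  # harmonic RC restraint at its target: zero energy and force
  rc <- reaction_coordinate("weighted_distance_sum", list(c("C2", "C8")), 1)
  bias <- restraint("harmonic_rc", rc = rc, target = 2.6,
                    force_constant = 200)
  out <- restraint_energy(bias, reg)
  expect_equal(out$energy, 0, tolerance = 1e-12)
  expect_lt(max(abs(out$forces)), 1e-12)
  # displaced: engine convention K (xi - xi0)^2, and forces match -dE/dx
  bias2 <- restraint("harmonic_rc", rc = rc, target = 2.0,
                     force_constant = 150)
  out2 <- restraint_energy(bias2, reg)
  expect_equal(out2$energy, 150 * 0.6^2, tolerance = 1e-12)
  # position anchor
  anchor <- restraint("position", pair = "C2", target = c(0.3, 0, 0),
                      force_constant = 10)
  outp <- restraint_energy(anchor, reg)
  expect_equal(outp$energy, 10 * 0.09, tolerance = 1e-12)
  expect_equal(outp$forces[1, 1], -2 * 10 * (-0.3), tolerance = 1e-12)
})

test_that("zero-temperature frictionless Langevin conserves energy", {
  k <- 50
  ff <- function(region) {
    x <- region$coordinates[1, ]
    list(energy = 0.5 * k * sum(x^2), forces = rbind(-k * x))
  }
  reg <- ml_region("C", matrix(c(0.4, 0, 0), 1, 3))
  m <- 12.011
  etot <- numeric(10000)
  rec <- function(step, region, vel, en) {
    etot[step] <<- en + 0.5 * m * sum(vel^2) / 4.184e-4
  }
  run_langevin(ff, reg, dt_fs = 0.5, n_steps = 10000,
               temperature = 0, friction_fs = 0, seed = 1, record = rec)
  # velocity-Verlet limit: bounded oscillation, no secular drift
  drift <- unname(stats::coef(stats::lm(etot ~ seq_along(etot)))[2]) * 10000
  expect_lt(abs(drift) / etot[1], 1e-6)
})

test_that("trajectories are bitwise reproducible for a fixed seed", {
  gt <- fx_gt()
  reg <- toy_equilibrium_region(gt$surface, "reactant")
  ff <- function(region) {
    out <- gt$surface$fun(region)
    list(energy = out$energy, forces = -out$gradient)
  }
  r1 <- run_langevin(ff, reg, dt_fs = 0.5, n_steps = 200,
                     temperature = 300, friction_fs = 0.05, seed = 77)
  r2 <- run_langevin(ff, reg, dt_fs = 0.5, n_steps = 200,
                     temperature = 300, friction_fs = 0.05, seed = 77)
  expect_identical(r1$region$coordinates, r2$region$coordinates)
  expect_identical(r1$energies, r2$energies)
  r3 <- run_langevin(ff, reg, dt_fs = 0.5, n_steps = 200,
                     temperature = 300, friction_fs = 0.05, seed = 78)
  expect_false(identical(r3$energies, r1$energies))
})

test_that("Langevin sampling satisfies equipartition in a harmonic well", {
  k_spring <- 10   # kcal/mol/A^2, potential k/2 x^2
  temperature <- 300
  ff <- function(region) {
    x <- region$coordinates[1, 1]
    f <- matrix(0, 1, 3)
    f[1, 1] <- -k_spring * region$coordinates[1, 1]
    # confine y, z tightly so only x matters
    f[1, 2:3] <- -500 * region$coordinates[1, 2:3]
    list(energy = 0.5 * k_spring * x^2 +
           250 * sum(region$coordinates[1, 2:3]^2), forces = f)
  }
  reg <- ml_region("C", matrix(0, 1, 3))
  xs <- numeric(200000)
  rec <- function(step, region, vel, en) xs[step] <<- region$coordinates[1, 1]
  run_langevin(ff, reg, dt_fs = 1.0, n_steps = length(xs),
               temperature = temperature, friction_fs = 0.1, seed = 11,
               record = rec)
  xs <- xs[-(1:20000)]
  expect_equal(mean(xs), 0, tolerance = 0.05)
  target <- 0.0019872041 * temperature / k_spring
  blocks <- matrix(xs[1:(length(xs) %/% 20 * 20)], ncol = 20)
  est <- colMeans(blocks^2)
  se <- sd(est) / sqrt(20)
  expect_lt(abs(mean(est) - target), 3 * se + 0.02 * target)
})
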