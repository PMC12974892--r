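test_that("window grids reproduce the documented inclusive counts", {
  expect_length(make_window_grid(1.3, 3.8, 0.1)$centers, 26)
  expect_length(make_window_grid(-4.5, 2.2, 0.1)$centers, 68)
  expect_length(make_window_grid(-2.5, 2.2, 0.1)$centers, 48)
  expect_length(make_window_grid(0, 1, 0.5)$centers, 3)
  expect_equal(make_window_grid(1.3, 3.8, 0.1)$centers[1:3],
               c(1.3, 1.4, 1.5), tolerance = 1e-12)
  expect_error(make_window_grid(0, 1, 0.3), "lattice")
})

test_that("umbrella sampling pins windows in the stiff-spring limit", {
  sys <- .line_system(function(x) 0, function(x) 0)
  win <- make_window_grid(1.5, 2.5, 0.25, force_constant = 3000)
  s <- .sample_line(sys, win, steps = 600, seed = 2)
  for (c in win$centers) {
    m <- mean(s$rc_value[s$window_center == c])
    expect_lt(abs(m - c), win$spacing / 10)
  }
  expect_length(attr(s, "non_overlapping"), 0)
})

test_that("per-window variance matches the Gaussian closed form", {
  k_well <- 40
  sys <- .line_system(function(x) 0.5 * k_well * (x - 2)^2,
                      function(x) k_well * (x - 2))
  win <- make_window_grid(2.0, 2.0, 0.1, force_constant = 100)
  s <- .sample_line(sys, win, steps = 8000, seed = 3)
  kt <- 0.0019872041 * 300
  # bias K (x-c)^2 contributes 2K to the curvature; well k/2 (x-2)^2 adds k
  var_expect <- kt / (k_well + 2 * 100)
  expect_equal(var(s$rc_value), var_expect, tolerance = 0.15)
})

test_that("replicas differ in samples but share window metadata", {
  sys <- .line_system(function(x) 0, function(x) 0)
  win <- make_window_grid(2, 2.2, 0.2, force_constant = 500)
  s <- .sample_line(sys, win, steps = 300, seed = 4, replicas = 2)
  s1 <- s[s$replica == 1 & s$window_center == 2, "rc_value"]
  s2 <- s[s$replica == 2 & s$window_center == 2, "rc_value"]
  expect_false(identical(s1, s2))
  expect_identical(unique(s$window_center), win$centers)
})

test_that("degenerate WHAM (one window, zero bias) is the log histogram", {
  set.seed(9)
  x <- rnorm(4000, mean = 2, sd = 0.15)
  samples <- data.frame(window_center = 2, replica = 1,
                        step = seq_along(x), rc_value = x)
  win <- make_window_grid(2, 2, 0.1, force_constant = 0)
  pr <- wham(samples, win, temperature = 300, bin_width = 0.05)
  kt <- 0.0019872041 * 300
  h <- hist(x, breaks = seq(min(x) - 1e-9, max(x) + 0.05, by = 0.05),
            plot = FALSE)
  ref <- -kt * log(h$counts[h$counts > 0])
  ref <- ref - min(ref)
  expect_equal(pr$free_energy, ref, tolerance = 1e-6)
})

test_that("WHAM recovers a harmonic PMF with the right curvature", {
  k_well <- 20
  sys <- .line_system(function(x) 0.5 * k_well * (x - 2)^2,
                      function(x) k_well * (x - 2))
  win <- make_window_grid(1.5, 2.5, 0.1, force_constant = 50)
  s <- .sample_line(sys, win, steps = 1500, seed = 6)
  pr <- wham(s, win, temperature = 300)
  sel <- abs(pr$rc_grid - 2) < 0.35
  fit <- lm(pr$free_energy[sel] ~ poly(pr$rc_grid[sel], 2, raw = TRUE))
  curv <- 2 * coef(fit)[3]
  expect_equal(unname(curv), k_well, tolerance = 0.1)
})

test_that("WHAM is stable under bin halving and refuses gapped windows", {
  k_well <- 20
  sys <- .line_system(function(x) 0.5 * k_well * (x - 2)^2,
                      function(x) k_well * (x - 2))
  win <- make_window_grid(1.6, 2.4, 0.1, force_constant = 50)
  s <- .sample_line(sys, win, steps = 4000, seed = 12)
  p1 <- wham(s, win, temperature = 300, bin_width = 0.05)
  p2 <- wham(s, win, temperature = 300, bin_width = 0.025)
  on_grid <- approx(p2$rc_grid, p2$free_energy, xout = p1$rc_grid,
                    rule = 2)$y
  sel <- p1$free_energy < 4
  expect_lt(max(abs(p1$free_energy[sel] - on_grid[sel])), 0.25)
  gapped <- s[s$window_center %in% win$centers[c(1, 2, 8, 9)], ]
  expect_error(wham(gapped, win, temperature = 300), "non-overlapping")
})

test_that("PMF statistics: barrier, reaction energy, gauge invariance", {
  pr <- structure(list(rc_grid = c(1, 2, 3), free_energy = c(0, 5, 2),
                       std = rep(NA_real_, 3), temperature = 300,
                       metadata = list()), class = "pmf_profile")
  st <- pmf_statistics(pr, reactant_range = c(0.5, 1.5),
                       product_range = c(2.5, 3.5), ts_range = c(1.5, 2.5))
  expect_identical(st$barrier, 5)
  expect_identical(st$reaction, 2)
  pr2 <- pr; pr2$free_energy <- pr$free_energy + 7
  st2 <- pmf_statistics(pr2, c(0.5, 1.5), c(2.5, 3.5), ts_range = c(1.5, 2.5))
  expect_identical(st2$barrier, st$barrier)
  expect_identical(st2$reaction, st$reaction)
  # monotone profile: no interior maximum
  mono <- structure(list(rc_grid = 1:6, free_energy = as.numeric(1:6),
                         std = rep(NA_real_, 6), temperature = 300,
                         metadata = list()), class = "pmf_profile")
  expect_error(pmf_statistics(mono, c(1, 2), c(5, 6)), "ts_range")
})

test_that("catalytic effects reproduce the reported differences", {
  expect_equal(catalytic_effect(23.3, 10.8), -12.5, tolerance = 1e-12)
  expect_equal(catalytic_effect(25.6, 12.8), -12.8, tolerance = 1e-12)
  expect_identical(catalytic_effect(14, 14), 0)
})

test_that("identical replicas give zero uncertainty", {
  set.seed(10)
  x <- rnorm(800, 2, 0.1)
  samples <- rbind(
    data.frame(window_center = 2, replica = 1, step = 1:800, rc_value = x),
    data.frame(window_center = 2, replica = 2, step = 1:800, rc_value = x))
  win <- make_window_grid(2, 2, 0.1, force_constant = 0)
  out <- pmf_uncertainty(samples, win, temperature = 300, method = "replica",
                         bin_width = 0.05)
  expect_lt(max(out$profile$std), 1e-10)
})

test_that("replica and fragment uncertainties agree on resampled series", {
  k_well <- 15
  sys <- .line_system(function(x) 0.5 * k_well * (x - 2)^2,
                      function(x) k_well * (x - 2))
  win <- make_window_grid(1.7, 2.3, 0.1, force_constant = 50)
  s5 <- .sample_line(sys, win, steps = 1000, seed = 21, replicas = 5)
  rep_out <- pmf_uncertainty(s5, win, temperature = 300, method = "replica")
  # concatenate the 5 replicas into one series per window; its 5 contiguous
  # fragments are exactly the replicas
  s_cat <- s5[order(s5$window_center, s5$replica, s5$step), ]
  s_cat$step <- ave(s_cat$rc_value, s_cat$window_center, FUN = seq_along)
  s_cat$replica <- 1
  frag_out <- pmf_uncertainty(s_cat, win, temperature = 300,
                              method = "fragment", n_fragments = 5)
  expect_equal(frag_out$profile$free_energy, rep_out$profile$free_energy,
               tolerance = 1e-6)
  expect_equal(frag_out$profile$std, rep_out$profile$std, tolerance = 1e-6)
})

test_that("fragment uncertainty shrinks roughly as one over sqrt(length)", {
  set.seed(30)
  win <- make_window_grid(2, 2, 0.1, force_constant = 0)
  sds <- vapply(c(500, 2000, 8000), function(n) {
    x <- rnorm(n, 2, 0.12)
    s <- data.frame(window_center = 2, replica = 1, step = seq_len(n),
                    rc_value = x)
    out <- pmf_uncertainty(s, win, temperature = 300, method = "fragment",
                           bin_width = 0.06)
    mean(out$profile$std[out$profile$free_energy < 2])
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  ratio <- sds[1] / sds[3]           # expect about sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
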