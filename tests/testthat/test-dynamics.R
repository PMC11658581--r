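two_node_connectome <- function() {
  connectome(data.frame(abbrev = c("A", "B")),
             data.frame(from = c("A", "B"), to = c("B", "A")))
}

test_that("uncoupled noiseless FHN stays at its fixed point", {
  cc <- two_node_connectome()
  r <- simulate_fhn(cc, fhn_params(k = 0, sigma = 0, alpha = 0,
                                   x0_range = c(0, 0), y0_range = c(0, 0),
                                   steps = 200))
  expect_equal(max(abs(r$act)), 0)
  expect_equal(max(abs(r$states$y)), 0)
})

test_that("FHN runs are seed-reproducible and noiseless runs deterministic", {
  cc <- generate_connectome(generator_config(n_regions = 10, n_links = 40,
                                             seed = 2))
  a <- simulate_fhn(cc, fhn_params(steps = 50, seed = 4))
  b <- simulate_fhn(cc, fhn_params(steps = 50, seed = 4))
  expect_identical(a$act, b$act)
  d1 <- simulate_fhn(cc, fhn_params(steps = 50, sigma = 0, seed = 1))
  d2 <- simulate_fhn(cc, fhn_params(steps = 50, sigma = 0, seed = 99))
  # with sigma = 0 the only seed effect is the initial condition draw
  expect_false(identical(d1$act, d2$act))
  d3 <- simulate_fhn(cc, fhn_params(steps = 50, sigma = 0, seed = 1))
  expect_identical(d1$act, d3$act)
})

test_that("two coupled FHN neurons sustain oscillations over a long run", {
  cc <- two_node_connectome()
  r <- simulate_fhn(cc, fhn_params(epsilon = 1, steps = 8000, seed = 9))
  late <- r$act[4001:8001, ]
  expect_gt(diff(range(late[, 1])), 1)       # nonzero amplitude after transient
  expect_gt(sum(diff(sign(late[, 1])) != 0), 50)  # keeps crossing zero
})

test_that("Euler-Maruyama noise variance grows linearly at small times", {
  cc <- two_node_connectome()
  base <- fhn_params(k = 0, sigma = 0, x0_range = c(0, 0), y0_range = c(0, 0),
                     steps = 20, euler_substeps = 1, dt = 0.01)
  det <- simulate_fhn(cc, base)
  vars <- sapply(1:40, function(s) {
    p <- base; p$sigma <- 0.5; p$seed <- s
    (simulate_fhn(cc, p)$act - det$act)[, 1]
  })
  v <- apply(vars, 1, var)
  # var(x_t - x_det) ~ sigma^2 * t for small t: ratio at 2 steps vs 10 steps
  expect_gt(v[11], 3 * v[3])
  fit <- lm(v ~ seq_along(v))
  expect_gt(summary(fit)$r.squared, 0.9)
})

test_that("spike detection thresholds at mean + z sd", {
  x <- matrix(rnorm(200, sd = 0.01), ncol = 2)
  x[50, 1] <- 10   # lone outlier far above mean + sd
  raster <- detect_spikes(x, z = 1)
  expect_equal(dim(raster), dim(x))
  expect_equal(which(raster[, 1] == 1), 50L)
  # constant trace: no spikes, flagged
  flat <- matrix(c(rep(1, 100), rnorm(100)), ncol = 2,
                 dimnames = list(NULL, c("F", "G")))
  rf <- detect_spikes(flat)
  expect_equal(sum(rf[, "F"]), 0)
  expect_equal(attr(rf, "flat_regions"), "F")
})

test_that("coactivation follows the union normalization", {
  r <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  co <- coactivation(r)
  expect_equal(co["a", "b"], 1 / 3)
  expect_equal(diag(co), c(a = 1, b = 1))
  # identical nonempty trains -> 1; disjoint trains -> 0
  expect_equal(coactivation(cbind(c(1, 0), c(1, 0)))[1, 2], 1)
  expect_equal(coactivation(cbind(c(1, 0), c(0, 1)))[1, 2], 0)
  # per-time mode divides by the sample count
  expect_equal(coactivation(r, "per_time")["a", "b"], 1 / 4)
  # empty pair flagged
  co0 <- coactivation(cbind(x = c(0, 0), y = c(1, 0)))
  expect_equal(co0["x", "y"], 0)
  expect_equal(attr(co0, "inactive_regions"), "x")
  expect_error(coactivation(cbind(c(0.5, 1))), "binary")
})

test_that("Wilson-Cowan converges to F(0) = 0.5 without input and stays bounded", {
  cc <- two_node_connectome()
  p <- wc_params(w_xx = 0, w_yx = 0, w_xy = 0, w_yy = 0,
                 I_ext_x = 0, I_ext_y = 0, k_net = 0, steps = 4000,
                 x0_range = c(0.1, 0.1), y0_range = c(0.9, 0.9))
  r <- simulate_wilson_cowan(cc, p)
  expect_equal(unname(r$act[nrow(r$act), ]), c(0.5, 0.5), tolerance = 1e-4)
  # sigmoid output with leak keeps activity inside (0, 1)
  r2 <- simulate_wilson_cowan(cc, wc_params(steps = 3000, seed = 2))
  expect_true(all(r2$act > 0 & r2$act < 1))
  # default regime oscillates rather than settling
  late <- r2$act[2000:3001, 1]
  expect_gt(diff(range(late)), 0.05)
})

test_that("Mimura-Murray keeps the uniform equilibrium exactly uniform", {
  cc <- generate_connectome(generator_config(n_regions = 12, n_links = 60,
                                             seed = 3))
  eq <- mm_equilibrium()
  p <- mm_params(P0 = c(eq["P"], eq["P"]), Q0 = c(eq["Q"], eq["Q"]),
                 solver = "euler", steps = 50)
  r <- simulate_mimura_murray(cc, p)
  expect_lt(max(abs(r$act - eq["P"])), 1e-8)
  expect_lt(max(abs(r$states$Q - eq["Q"])), 1e-8)
})

test_that("a single isolated node reproduces a reference ODE solution", {
  cc <- connectome(data.frame(abbrev = "A"))
  p <- mm_params(P0 = c(6, 6), Q0 = c(12, 12), steps = 30, solver = "dopri45",
                 rtol = 1e-11, atol = 1e-11)
  r <- simulate_mimura_murray(cc, p)
  ref <- deSolve::ode(
    y = c(P = 6, Q = 12), times = r$time,
    func = function(t, y, parms) {
      with(as.list(y), list(c(((13 + 16 * P - P^2) / 9 - Q) * P,
                              (P - (1 + 0.4 * Q)) * Q)))
    }, parms = NULL, method = "lsoda", rtol = 1e-11, atol = 1e-11)
  expect_lt(max(abs(r$act[, 1] - ref[, "P"])), 1e-6)
  expect_lt(max(abs(r$states$Q[, 1] - ref[, "Q"])), 1e-6)
})

test_that("Mimura-Murray trajectories stay non-negative", {
  cc <- generate_connectome(generator_config(n_regions = 16, n_links = 90,
                                             seed = 7))
  r <- simulate_mimura_murray(cc, mm_params(steps = 300,
                                            stimulus_region = "R001_R"))
  expect_gte(min(r$act), -1e-6)
  expect_gte(min(r$states$Q), -1e-6)
})

test_that("the Kuramoto order parameter matches closed-form cases", {
  t <- seq(0, 20, by = 0.01)
  sync <- cbind(a = sin(2 * pi * t), b = sin(2 * pi * t))
  expect_gt(kuramoto_index(sync)$mean, 0.999)
  anti <- cbind(a = sin(2 * pi * t), b = sin(2 * pi * t + pi))
  expect_lt(kuramoto_index(anti)$mean, 0.01)
  # independent phases: R ~ N^(-1/2)
  set.seed(5)
  N <- 64
  indep <- sapply(seq_len(N), function(i) sin(2 * pi * t + runif(1, 0, 2 * pi)))
  R <- kuramoto_index(indep)$mean
  expect_lt(R, 3 / sqrt(N))
  # constant trace dropped with a warning
  expect_warning(ki <- kuramoto_index(cbind(a = sin(t), b = sin(t + 1),
                                            c = rep(1, length(t)))),
                 "constant")
  expect_equal(ki$dropped, "c")
  expect_true(all(ki$R >= 0 & ki$R <= 1 + 1e-12))
})

test_that("summary measures are coherent and reproducible", {
  cc <- generate_connectome(generator_config(n_regions = 12, n_links = 70,
                                             seed = 4))
  r <- simulate_fhn(cc, fhn_params(steps = 200, seed = 6))
  s1 <- summary_measures(r)
  s2 <- summary_measures(simulate_fhn(cc, fhn_params(steps = 200, seed = 6)))
  expect_identical(s1, s2)
  expect_true(s1$mean_coactivation >= 0 && s1$mean_coactivation <= 1)
  expect_true(s1$mean_kuramoto >= 0 && s1$mean_kuramoto <= 1)
  # an all-zero raster yields zero mean coactivation
  expect_equal(mean(coactivation(matrix(0, 10, 3))), 0)
})
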