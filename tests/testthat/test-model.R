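cfg <- test_cfg()

test_that("rhs vanishes in the absorbing zero state and balances production", {
  p0 <- c(bas1 = 0, bas2 = 1, Ky = 0, Kmy = 1, Kt = 0.5)
  expect_equal(lac_rhs(c(0, 0, 0), p0, cfg), c(0, 0, 0))

  # no extracellular and no intracellular lactose: lactose flux is zero
  cfg0 <- test_cfg(fixed = list(lac_out = 0))
  d <- lac_rhs(c(3, 2, 0), c(bas1 = 0.1, bas2 = 1, Ky = 2, Kmy = 1, Kt = 0.5),
               cfg0)
  expect_identical(d[3], 0)

  # production balancing degradation: bas1 = kd1 * LacZ, no activation
  cfg1 <- test_cfg(fixed = list(kd1 = 1))
  d <- lac_rhs(c(1, 0, 0), c(bas1 = 1, bas2 = 1, Ky = 0, Kmy = 1, Kt = 0.5),
               cfg1)
  expect_equal(d[1], 0)
})

test_that("rhs rejects non-finite inputs", {
  p <- c(bas1 = 0.1, bas2 = 1, Ky = 2, Kmy = 1, Kt = 0.5)
  expect_error(lac_rhs(c(NA, 0, 0), p, cfg), "finite")
  expect_error(lac_rhs(c(0, 0), p, cfg), "finite")
  p[["Ky"]] <- Inf
  expect_error(lac_rhs(c(0, 0, 0), p, cfg), "finite")
})

test_that("total LacI takes its closed form bas2/kd3", {
  cfg2 <- test_cfg(fixed = list(kd3 = 2))
  ss <- steady_state(c(bas1 = 0.1, bas2 = 10, Ky = 2, Kmy = 1, Kt = 0.5), cfg2)
  expect_identical(ss$lacI_tot, 10 / 2)
})

test_that("without extracellular lactose the system is fully closed-form", {
  cfg0 <- test_cfg(fixed = list(lac_out = 0))
  p <- c(bas1 = 0.2, bas2 = 1, Ky = 5, Kmy = 2, Kt = 0.5)
  ss <- steady_state(p, cfg0)
  expect_identical(ss$lac_in, 0)
  expect_equal(ss$lacI_free, ss$lacI_tot)
  expect_equal(ss$lacZ,
               (p[["bas1"]] + p[["Ky"]] / (p[["Kmy"]] + 1 / cfg0$fixed$kd3)) /
                 cfg0$fixed$kd1)
  # agrees with long-horizon time integration
  ssi <- steady_state(p, cfg0, method = "integrate")
  expect_equal(ss$lacZ, ssi$lacZ, tolerance = 1e-8)
  expect_equal(ssi$lac_in, 0, tolerance = 1e-8)
  # benefit is zero, fitness is pure cost
  fb <- compute_fitness(p, cfg0)
  expect_identical(fb$benefit, 0)
  expect_lte(fb$fitness, 0)
  expect_equal(fb$fitness, -fb$cost)
})

test_that("no production means an empty expression state and repressor-only cost", {
  p <- c(bas1 = 0, bas2 = 1, Ky = 0, Kmy = 1, Kt = 0.5)
  ss <- steady_state(p, cfg)
  expect_identical(ss$lacZ, 0)
  expect_identical(ss$lacY, 0)
  expect_identical(ss$lac_in, 0)
  fb <- compute_fitness(p, cfg)
  expect_equal(fb$fitness,
               -cfg$cost$alpha * cfg$cost$alpha_i * (1 / cfg$fixed$kd3))
})

test_that("analytic, root-finding and integration methods agree", {
  pts <- random_params(10, cfg, seed = 3)
  sa <- steady_state(pts, cfg, method = "analytic")
  sr <- steady_state(pts, cfg, method = "root")
  si <- steady_state(pts, cfg, method = "integrate")
  for (col in c("lacZ", "lacY", "lacI_tot", "lacI_free", "lac_in")) {
    expect_equal(sr[[col]], sa[[col]], tolerance = 1e-9)
    expect_equal(si[[col]], sa[[col]], tolerance = 1e-6)
  }
  expect_true(all(sa$converged))
})

test_that("steady-state species are nonnegative across the box and repression is monotone", {
  pts <- random_params(200, cfg, seed = 5)
  ss <- steady_state(pts, cfg)
  expect_true(all(ss$converged))
  for (col in c("lacZ", "lacY", "lacI_tot", "lacI_free", "lac_in")) {
    expect_true(all(ss[[col]] >= 0))
  }
  expect_true(all(ss$lacI_free <= ss$lacI_tot))
  # free = total only when intracellular lactose is absent
  expect_identical(ss$lacI_free == ss$lacI_tot, ss$lac_in == 0)

  # increasing the repressor supply weakly decreases LacZ, all else fixed
  base <- c(bas1 = 0.1, bas2 = 0.2, Ky = 5, Kmy = 1, Kt = 0.5)
  bas2_grid <- seq(0.001, 2, length.out = 25)
  lacZ <- vapply(bas2_grid, function(b) {
    q <- base
    q[["bas2"]] <- b
    steady_state(q, cfg)$lacZ
  }, numeric(1))
  expect_true(all(diff(lacZ) <= 1e-12))
})

test_that("benefit follows its saturating kinetics and cost its linear form", {
  # k3 = 2, lacZ = 3, lac_in = 1, k4 = 1 -> benefit 3
  cfgb <- test_cfg(fixed = list(k3 = 2, k4 = 1))
  ss <- tibble::tibble(lacZ = 3, lacY = 0, lacI_tot = 0, lacI_free = 0,
                       lac_in = 1, converged = TRUE)
  expect_equal(compute_benefit(ss, cfgb), 3)
  # zero enzyme or zero substrate: zero benefit
  ss0 <- dplyr::mutate(ss, lacZ = 0)
  expect_equal(compute_benefit(ss0, cfgb), 0)
  # saturation bound: benefit <= k3 * lacZ for any lac_in
  for (L in c(0, 0.1, 10, 1e6)) {
    ssL <- dplyr::mutate(ss, lac_in = L)
    expect_lte(compute_benefit(ssL, cfgb), 2 * 3)
  }
  # degenerate half-saturation is an error
  cfgd <- test_cfg(fixed = list(k4 = 0))
  expect_error(compute_benefit(dplyr::mutate(ss, lac_in = 0), cfgd),
               "degenerate")

  cfgc <- test_cfg(cost = list(alpha = 1, alpha_z = 1, alpha_y = 1,
                               alpha_i = 1))
  ssc <- tibble::tibble(lacZ = 1, lacY = 2, lacI_tot = 3, lacI_free = 3,
                        lac_in = 0, converged = TRUE)
  expect_equal(compute_cost(ssc, cfgc), 6)
  cfg0 <- test_cfg(cost = list(alpha = 0))
  expect_equal(compute_cost(ssc, cfg0), 0)
})

test_that("fitness is benefit minus cost and never exceeds benefit", {
  pts <- random_params(100, cfg, seed = 11)
  fb <- compute_fitness(pts, cfg)
  expect_equal(fb$fitness, fb$benefit - fb$cost)
  expect_true(all(fb$fitness <= fb$benefit))
  expect_true(all(fb$cost >= 0))
  expect_true(all(fb$benefit >= 0))
})

test_that("influx beyond metabolic capacity is flagged as non-converged", {
  # with k3 small the lactose balance has no finite steady state at high Kt
  cfgx <- test_cfg(fixed = list(k3 = 0.1))
  p <- c(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.9)
  ss <- steady_state(p, cfgx)
  expect_false(ss$converged)
  expect_true(is.na(ss$lac_in))
  ssr <- steady_state(p, cfgx, method = "root")
  expect_false(ssr$converged)
  fb <- compute_fitness(p, cfgx)
  expect_true(is.na(fb$fitness))
})
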