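cfg <- test_cfg()
bg <- c(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 0.5)

test_that("the kernel picks each parameter uniformly and stays in range", {
  m <- propose_mutations(bg, 1e5, cfg, seed = 1)
  counts <- table(m$param_id)
  expect_setequal(names(counts), mutable_params())
  # equal-probability choice among the five parameters
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
  expect_true(all(abs(counts / 1e5 - 0.2) < 0.005))
  # proposals respect the configured ranges
  for (nm in mutable_params()) {
    r <- cfg$mutable[[nm]]
    v <- m$new_value[m$param_id == nm]
    expect_true(all(v >= r[1] & v <= r[2]))
  }
  # exactly one parameter changes per mutation: old values match background
  expect_equal(m$old_value, unname(bg[m$param_id]))
})

test_that("a vanishing kernel width degenerates to the identity", {
  cfg_tiny <- test_cfg(kernel = list(cv = 1e-12))
  m <- propose_mutations(bg, 100, cfg_tiny, seed = 2)
  expect_equal(m$new_value, m$old_value, tolerance = 1e-9)
})

test_that("a zero-valued parameter falls back to a range-width proposal std", {
  bg0 <- c(bas1 = 0.1, bas2 = 0.5, Ky = 0, Kmy = 1, Kt = 0.5)
  m <- propose_mutations(bg0, 2e4, cfg, seed = 3)
  v <- m$new_value[m$param_id == "Ky"]
  expect_gt(length(v), 100)
  expect_true(all(is.finite(v)))
  expect_gt(stats::sd(v), 0.1) # proposals really move off zero
})

test_that("proposals from a boundary value stay inside under both policies", {
  bg_hi <- c(bas1 = 0.1, bas2 = 0.5, Ky = 5, Kmy = 1, Kt = 1) # Kt at max
  for (pol in c("resample", "clip")) {
    cfgp <- test_cfg(kernel = list(policy = pol))
    m <- propose_mutations(bg_hi, 5000, cfgp, seed = 4)
    v <- m$new_value[m$param_id == "Kt"]
    expect_true(all(v <= 1 & v >= 0.01))
  }
})

test_that("DFE construction is deterministic, conservative, and excludes failures", {
  d1 <- build_dfe(bg, 2000, cfg, seed = 5)
  d2 <- build_dfe(bg, 2000, cfg, seed = 5)
  expect_identical(d1$delta_fitness, d2$delta_fitness)
  expect_identical(attr(d1, "n_failed"), 0L)

  cls <- classify_dfe(d1)
  expect_equal(cls$fraction_beneficial + cls$fraction_deleterious +
                 cls$fraction_neutral, 1)
  expect_identical(cls$n, nrow(d1))
  # classification column is consistent with the stored deltas
  expect_identical(d1$effect == "beneficial", d1$delta_fitness > 0)
  expect_identical(d1$effect == "deleterious", d1$delta_fitness < 0)

  # empty sample contract
  d0 <- build_dfe(bg, 0, cfg, seed = 5)
  expect_identical(nrow(d0), 0L)
  expect_error(classify_dfe(d0), "empty")
})

test_that("classification respects the neutral threshold", {
  d <- build_dfe(bg, 500, cfg, seed = 6)
  # a huge epsilon declares everything neutral
  cls <- classify_dfe(d, neutral_epsilon = 1e12)
  expect_equal(cls$fraction_neutral, 1)
  expect_equal(cls$fraction_beneficial, 0)
  # hand-built two-point sample splits evenly at epsilon 0
  toy <- lacdfe:::new_lac_dfe(
    tibble::tibble(param_id = c("Ky", "Ky"), old_value = c(1, 1),
                   new_value = c(2, 0.5), fitness = c(2, 0),
                   delta_fitness = c(1, -1), effect = c("beneficial", "deleterious")),
    bg, 1, 0, 0L)
  cls2 <- classify_dfe(toy)
  expect_equal(cls2$fraction_beneficial, 0.5)
  expect_equal(cls2$fraction_deleterious, 0.5)
  expect_equal(cls2$fraction_neutral, 0)
})

test_that("at the fitness optimum almost no mutation is beneficial", {
  fm <- estimate_fmax(cfg, n_starts = 16L, seed = 1)
  d <- build_dfe(unlist(fm$par), 2000, cfg, seed = 7)
  cls <- classify_dfe(d)
  expect_lt(cls$fraction_beneficial, 0.01)
})

test_that("glance on a DFE reports background fitness and fractions", {
  d <- build_dfe(bg, 300, cfg, seed = 8)
  g <- glance(d)
  expect_equal(g$background_fitness, compute_fitness(bg, cfg)$fitness)
  expect_true(all(c("fraction_beneficial", "mean_beneficial_s") %in% names(g)))
})
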