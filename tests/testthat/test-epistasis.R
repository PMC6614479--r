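cfg <- test_cfg()

# an interior positive-fitness background where every parameter still has
# beneficial mutations available
p0 <- c(bas1 = 0.36, bas2 = 0.66, Ky = 16.9, Kmy = 9.1, Kt = 0.98)

test_that("found beneficial mutations really are beneficial when re-scored", {
  f0 <- compute_fitness(p0, cfg)$fitness
  for (fp in c("Ky", "Kt", "bas2")) {
    m <- find_beneficial_mutation(p0, fp, cfg, seed = 2)
    q <- p0
    q[fp] <- m$new_value
    f1 <- compute_fitness(q, cfg)$fitness
    expect_gt(f1, f0)
    expect_equal(m$delta_fitness, f1 - f0, tolerance = 1e-12)
  }
})

test_that("no beneficial mutation exists at a 1-D optimum within budget", {
  fm <- estimate_fmax(cfg, n_starts = 16L, seed = 1)
  expect_error(
    find_beneficial_mutation(unlist(fm$par), "Ky", cfg, seed = 3,
                             max_draws = 300),
    class = "lacdfe_no_beneficial")
})

test_that("an additive fitness function shows no epistasis at all", {
  add_fn <- function(df) {
    2 * df$bas1 + 3 * df$bas2 + 0.5 * df$Ky + 0.1 * df$Kmy + df$Kt
  }
  foc <- tibble::tibble(param_id = "Ky", old_value = p0[["Ky"]],
                        new_value = p0[["Ky"]] * 1.1,
                        delta_fitness = 0.5 * 0.1 * p0[["Ky"]])
  sc <- epistasis_scan(p0, foc, n_backgrounds = 40, config = cfg, seed = 4,
                       fitness_fn = add_fn)
  expect_equal(nrow(sc), 40L)
  expect_true(all(abs(sc$ratio - 1) < 1e-12))
  expect_false(any(sc$sign_epistatic))
})

test_that("scan records are self-consistent and reuse the focal value verbatim", {
  sc <- epistasis_scan(p0, "Ky", n_backgrounds = 24, config = cfg, seed = 5)
  # the focal mutation is bit-identical across backgrounds
  expect_identical(length(unique(sc$focal_new)), 1L)
  # backgrounds spread evenly over the four non-focal parameters
  expect_setequal(unique(sc$background_param), setdiff(mutable_params(), "Ky"))
  expect_true(all(table(sc$background_param) == 6L))
  # recomputing all four fitness values reproduces the stored ones
  for (i in c(1L, 7L, 24L)) {
    pM <- p0
    pM[sc$background_param[i]] <- sc$background_new[i]
    pMs <- pM
    pMs["Ky"] <- sc$focal_new[i]
    p0s <- p0
    p0s["Ky"] <- sc$focal_new[i]
    expect_equal(compute_fitness(p0, cfg)$fitness, sc$f0[i], tolerance = 1e-9)
    expect_equal(compute_fitness(p0s, cfg)$fitness, sc$f0_star[i],
                 tolerance = 1e-9)
    expect_equal(compute_fitness(pM, cfg)$fitness, sc$fM[i], tolerance = 1e-9)
    expect_equal(compute_fitness(pMs, cfg)$fitness, sc$fM_star[i],
                 tolerance = 1e-9)
  }
  expect_equal(sc$delta_f, sc$f0_star - sc$f0)
  expect_equal(sc$delta_f_star, sc$fM_star - sc$fM)
  # determinism
  sc2 <- epistasis_scan(p0, "Ky", n_backgrounds = 24, config = cfg, seed = 5)
  expect_identical(as.data.frame(sc), as.data.frame(sc2))
})

test_that("negligible background mutations leave the focal effect unchanged", {
  cfg_tiny <- test_cfg(kernel = list(cv = 1e-7))
  foc <- find_beneficial_mutation(p0, "Ky", cfg, seed = 6)
  sc <- epistasis_scan(p0, foc, n_backgrounds = 12, config = cfg_tiny,
                       seed = 6)
  expect_true(all(abs(sc$ratio - 1) < 1e-3))
})

test_that("ratios cluster by the parameter carrying the background mutation", {
  sc <- epistasis_scan(p0, "Ky", n_backgrounds = 120, config = cfg, seed = 7)
  # bas1 enters promoter activity additively, so it cannot interact with an
  # activity-channel focal mutation: its cluster sits exactly at ratio 1
  r_bas1 <- sc$ratio[sc$background_param == "bas1"]
  expect_true(all(abs(r_bas1 - 1) < 1e-9))
  # the groups are statistically distinct clusters
  kw <- stats::kruskal.test(sc$ratio, factor(sc$background_param))
  expect_lt(kw$p.value, 1e-6)
})

test_that("the ranked trend table orders by background fitness", {
  sc <- epistasis_scan(p0, "Kt", n_backgrounds = 30, config = cfg, seed = 8)
  tr <- ratio_vs_background_fitness(sc)
  expect_true(!is.unsorted(tr$fM))
  expect_identical(tr$rank, seq_len(nrow(tr)))
  expect_identical(attr(tr, "n_undefined"), sum(is.na(sc$ratio)))
  expect_false(attr(tr, "all_fM_equal"))
  # degenerate all-equal case is flagged and keeps input order
  fake <- sc[1:3, ]
  fake$fM <- 5
  fake$ratio <- c(2, 1, 3)
  tr2 <- ratio_vs_background_fitness(fake)
  expect_true(attr(tr2, "all_fM_equal"))
  expect_identical(tr2$ratio, c(2, 1, 3))
  expect_error(ratio_vs_background_fitness(sc[0, ]), ">= 2")
})

test_that("sign-epistatic flags require opposite effect signs", {
  sc <- epistasis_scan(p0, "Ky", n_backgrounds = 60, config = cfg, seed = 9)
  flagged <- sc$sign_epistatic
  expect_identical(flagged, sign(sc$delta_f) != sign(sc$delta_f_star))
})
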