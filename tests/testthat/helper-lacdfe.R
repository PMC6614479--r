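# Shared fixtures: everything is generated in code at test time.

test_cfg <- function(...) lac_config(...)

# n uniform draws inside the mutable box, as a tibble
random_params <- function(n, cfg, seed = 1) {
  b <- withr::with_seed(seed, {
    vapply(mutable_params(), function(nm) {
      r <- cfg$mutable[[nm]]
      stats::runif(n, r[1], r[2])
    }, numeric(n))
  })
  tibble::as_tibble(as.data.frame(matrix(b, nrow = n,
                                         dimnames = list(NULL, mutable_params()))))
}

# a low-fitness background with every coordinate strictly interior, found by
# single-coordinate crossing (no greedy climb), so beneficial mutations are
# available in all five parameters
interior_low_fitness_set <- function(cfg, fmax, seed = 7, n_try = 10) {
  sets <- sample_at_fitness(cfg, fraction = 0.001, count = n_try,
                            fmax = fmax, seed = seed)
  for (i in seq_len(nrow(sets))) {
    p0 <- unlist(sets[i, mutable_params()])
    ok <- all(vapply(mutable_params(), function(fp) {
      !inherits(tryCatch(
        find_beneficial_mutation(p0, fp, cfg, seed = 1, max_draws = 200),
        error = function(e) e), "error")
    }, logical(1)))
    if (ok) return(p0)
  }
  stop("no interior low-fitness set found")
}
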