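# Power-loop tests run at a reduced scale (small arms, few replicates,
# short permutation streams) so the whole file stays in seconds; the
# full-scale behaviour is exercised by the acceptance suite.

small_scenario <- function(...) {
  scenario_config(threshold_fractions = c(0, 0.5, 1e6),
                  n_per_arm = 8L, n_replicates = 40L,
                  n_permutations = 199L, master_seed = 2024L, ...)
}

test_that("scenario config validates its grid", {
  expect_error(scenario_config(threshold_fractions = c(0.5, 0.25)),
               "increasing")
  expect_error(scenario_config(threshold_fractions = c(-1, 0)), "fractions")
  expect_error(scenario_config(n_per_arm = 1), "n_per_arm")
  expect_error(scenario_config(alpha = 0), "alpha")
  expect_error(scenario_config(n_permutations = 0), "n_permutations")
})

test_that("power tables are reproducible and structurally sound", {
  gen <- tiny_gen()
  sce <- small_scenario()
  res1 <- run_scenario(sce, gen)
  res2 <- run_scenario(sce, gen)
  expect_identical(res1, res2)
  expect_equal(nrow(res1), 3 * 2)  # 3 fractions x 2 modes
  expect_true(all(res1$power >= 0 & res1$power <= 1))
  expect_equal(res1$mc_se,
               sqrt(res1$power * (1 - res1$power) / res1$n_replicates))
})

test_that("an absurd threshold forces all-neutral pairs and zero power", {
  gen <- tiny_gen()
  res <- run_scenario(small_scenario(), gen)
  huge <- res[res$threshold_fraction == 1e6, ]
  expect_true(all(huge$power == 0))
  expect_true(all(huge$mean_delta == 0))
})

test_that("under the null, rejection stays near alpha and the effect scenario has power", {
  gen <- tiny_gen()
  sce <- scenario_config(threshold_fractions = c(0, 0.75),
                         n_per_arm = 10L, n_replicates = 120L,
                         n_permutations = 399L, master_seed = 77L)
  null_res <- run_scenario(sce, gen, null = TRUE)
  band <- 3 * sqrt(0.05 * 0.95 / sce$n_replicates)
  expect_true(all(abs(null_res$power - 0.05) <= band + 1e-9))
  # strong standardized effects at n = 10/arm: power far above alpha
  eff <- run_scenario(sce, gen)
  f0 <- eff[eff$threshold_fraction == 0, ]
  expect_true(all(f0$power > 0.5))
})

test_that("marginal power isolates single domains", {
  # domain b carries no effect: its marginal power must sit near alpha
  gen <- tiny_gen()
  gen2 <- generator_config(domains = gen$domains,
                           baseline_mean = gen$baseline_mean,
                           slope_control = gen$slope_control,
                           slope_treated = c(3, gen$slope_control[2], -1.2),
                           direction = gen$direction,
                           sd_baseline_re = gen$sd_baseline_re,
                           sd_slope_re = gen$sd_slope_re,
                           sd_residual = gen$sd_residual)
  sce <- scenario_config(threshold_fractions = 0, n_per_arm = 10L,
                         n_replicates = 120L, n_permutations = 399L,
                         master_seed = 31L)
  marg <- run_marginal_power(sce, gen2)
  expect_equal(nrow(marg), 3)
  pb <- marg$power[marg$scenario == "b"]
  expect_lt(pb, 0.05 + 3 * sqrt(0.05 * 0.95 / 120) + 1e-9)
  expect_gt(marg$power[marg$scenario == "a"], pb)
})

test_that("expressive language dominates the default marginal powers at f = 0", {
  # scaled to 150 replicates / B = 399; the margin between the language
  # curve (~0.9) and the runner-up (~0.5) dwarfs the Monte Carlo error
  gen <- generator_config()
  sce <- scenario_config(threshold_fractions = 0, n_per_arm = 23L,
                         n_replicates = 150L, n_permutations = 399L,
                         master_seed = 606L)
  marg <- run_marginal_power(sce, gen)
  lang <- marg$power[marg$scenario == "expressive_language"]
  others <- marg$power[marg$scenario != "expressive_language"]
  expect_true(all(lang > others + 3 * sqrt(2) * max(marg$mc_se)))
})

test_that("ordering sensitivity shares replicates and reports deciding levels", {
  gen <- tiny_gen()
  sce <- small_scenario()
  out <- run_ordering_sensitivity(sce, gen,
                                  orderings = list(1:3, 3:1))
  expect_equal(sort(unique(out$power$ordering)), c("123", "321"))
  # identity ordering must agree exactly with run_scenario's prioritized
  # arm on the shared replicates (common random numbers)
  base <- run_scenario(sce, gen)
  base_pr <- base[base$mode == "prioritized", ]
  sens_123 <- out$power[out$power$ordering == "123", ]
  expect_equal(sens_123$power, base_pr$power)
  expect_equal(sens_123$mean_delta, base_pr$mean_delta)
  # deciding-level masses sum to the number of pairs per threshold
  dec <- out$deciding
  for (f in unique(dec$threshold_fraction)) {
    for (o in unique(dec$ordering)) {
      m <- dec$mean_pairs[dec$threshold_fraction == f & dec$ordering == o]
      expect_equal(sum(m), sce$n_per_arm^2)
    }
  }
  expect_error(run_ordering_sensitivity(sce, gen,
                                        orderings = list(1:3, 1:3)),
               "duplicate")
  expect_error(run_ordering_sensitivity(sce, gen,
                                        orderings = list(c(1, 1, 2))),
               "permutation")
})
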