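test_that("generator config resolves calibrated defaults and validates", {
  gen <- generator_config()
  expect_length(gen$domains, 5)
  # calibration: standardized slope shift equals std_effect exactly
  shift <- abs(gen$slope_treated - gen$slope_control)
  expect_equal(unname(shift / rate_sd(gen)), gen$std_effect)
  # the default language rate SD: |3.53 - 1.31| / 1.0
  expect_equal(unname(rate_sd(gen)[1]), 2.22)
  expect_error(generator_config(cross_domain_corr = 1), "cross_domain_corr")
  expect_error(generator_config(sd_residual = -1, sd_slope_re = 1), "SDs")
  expect_error(generator_config(visit_months = c(0, 6, 12)), "24")
  expect_error(generator_config(direction = 2), "direction")
})

test_that("deterministic limit reproduces the fixed-effect trajectory", {
  gen <- generator_config(sd_baseline_re = 0, sd_slope_re = 0,
                          sd_residual = 0)
  dat <- generate_arm(gen, "control", n = 2)
  lang <- dat[dat$domain == "expressive_language", ]
  # control expressive language: exactly 63 + 1.31 t, so 65.62 at month 24
  expect_equal(lang$score[lang$visit_month == 0], c(63, 63))
  expect_equal(lang$score[lang$visit_month == 24], c(65.62, 65.62))
  # treated sleep slope: every subject's derived rate is exactly -0.47
  trt <- generate_arm(gen, "treated", n = 3)
  r <- derive_rates(trt)
  expect_equal(r$sleep, rep(-0.47, 3))
  expect_equal(r$expressive_language, rep(3.53, 3))
  # quadratic term enters the derived rate as an additive 2 q shift
  genq <- generator_config(sd_baseline_re = 0, sd_slope_re = 0,
                           sd_residual = 0, quad_coef = 0.5)
  rq <- derive_rates(generate_arm(genq, "control", n = 1))
  expect_equal(unname(as.numeric(rq[1, gen$domains])),
               gen$slope_control + 2 * 0.5)
})

test_that("generation is seed-reproducible and n = 0 gives empty data", {
  gen <- tiny_gen()
  a <- generate_arm(gen, "treated", 5, seed = 123)
  b <- generate_arm(gen, "treated", 5, seed = 123)
  expect_identical(a, b)
  expect_identical(nrow(generate_arm(gen, "control", 0)), 0L)
  # complete grid: every subject x visit x domain exactly once
  tab <- table(a$subject_id, a$visit_month, a$domain)
  expect_true(all(tab == 1))
})

test_that("derive_rates matches hand computation and flags missing visits", {
  d <- data.frame(subject_id = "s1", arm = "control",
                  visit_month = c(0, 24), domain = "a",
                  score = c(63, 65.62))
  r <- derive_rates(d)
  expect_equal(r$a, 1.31)
  flat <- transform(d, score = c(5, 5))
  expect_equal(derive_rates(flat)$a, 0)
  broken <- d[d$visit_month == 0, ]
  expect_error(derive_rates(broken), "s1.*a|missing endpoint")
})

test_that("analytic rate SD is exact and the empirical mode agrees", {
  g1 <- tiny_gen(sd_slope_re = 1, sd_residual = 0)
  expect_equal(unname(rate_sd(g1)), rep(1, 3))
  g2 <- tiny_gen(sd_slope_re = 0, sd_residual = 2)
  expect_equal(unname(rate_sd(g2)), rep(sqrt(2), 3))
  # pilot-simulation oracle (scaled to 20,000 subjects; the tolerance is
  # 3 MC SEs of an SD estimate at that n, se ~ sd / sqrt(2 n))
  gen <- tiny_gen()
  n_pilot <- 20000L
  emp <- rate_sd(gen, "empirical", n_pilot = n_pilot, seed = 5)
  ana <- rate_sd(gen)
  se <- ana / sqrt(2 * (n_pilot - 1))
  expect_true(all(abs(emp - ana) < 3 * se))
})

test_that("large-sample rate means recover the configured slopes", {
  gen <- tiny_gen()
  n <- 4000L
  for (arm in c("control", "treated")) {
    r <- derive_rates(generate_arm(gen, arm, n, seed = 17))
    slopes <- if (arm == "treated") gen$slope_treated else gen$slope_control
    mc_se <- rate_sd(gen) / sqrt(n)
    got <- colMeans(as.matrix(r[, gen$domains]))
    expect_true(all(abs(got - slopes) < 3.5 * mc_se))
  }
})

test_that("cross-domain correlation propagates into the rates", {
  base <- tiny_gen(cross_domain_corr = 0.6)
  none <- tiny_gen(cross_domain_corr = 0)
  n <- 3000L
  r1 <- as.matrix(derive_rates(generate_arm(base, "control", n,
                                            seed = 19))[, base$domains])
  r0 <- as.matrix(derive_rates(generate_arm(none, "control", n,
                                            seed = 19))[, none$domains])
  c1 <- cor(r1)[upper.tri(diag(3))]
  c0 <- cor(r0)[upper.tri(diag(3))]
  expect_true(all(c1 > 0.1))          # clearly positive
  expect_true(all(abs(c0) < 0.06))    # near zero without shared effects
  expect_true(mean(c1) > mean(c0))
})

test_that("longitudinal data round-trips through CSV", {
  gen <- tiny_gen()
  dat <- generate_arm(gen, "treated", 3, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_longitudinal(dat, path)
  back <- read_longitudinal(path)
  expect_equal(back$score, dat$score)
  expect_equal(back$subject_id, dat$subject_id)
  expect_equal(derive_rates(back), derive_rates(dat))
})
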