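test_that("composite rate is additive, saturating and monotone", {
  one <- tibble::tibble(kcat = 100, Km = 500, weight = 1)
  expect_equal(composite_rate(one, 500), 50)  # half saturation
  expect_equal(composite_rate(one, 1e9), 100, tolerance = 1e-6)
  expect_error(composite_rate(one, -1), "non-negative")

  # equal-Km states pool algebraically
  two <- tibble::tibble(kcat = c(40, 120), Km = c(300, 300),
                        weight = c(0.7, 0.3))
  s <- c(10, 100, 1000)
  pooled <- (0.7 * 40 + 0.3 * 120) * s / (300 + s)
  expect_equal(composite_rate(two, s), pooled)

  # monotone nondecreasing in S and in every kcat
  mixed <- tibble::tibble(kcat = c(20, 60, 100), Km = c(200, 500, 900),
                          weight = c(0.2, 0.5, 0.3))
  grid <- seq(0, 5000, by = 50)
  expect_true(all(diff(composite_rate(mixed, grid)) >= 0))
  bumped <- mixed
  for (i in 1:3) {
    bumped$kcat[i] <- mixed$kcat[i] + 10
    expect_true(all(composite_rate(bumped, grid) >=
                      composite_rate(mixed, grid)))
    bumped$kcat[i] <- mixed$kcat[i]
  }
})

test_that("state ordering matches the additive stimulation pattern", {
  # basal < +RimA ~ +cdG < +RimA+cdG at matched substrate
  m <- make_model("four_state")
  conds <- list(basal = c(RimK = 1, RimA = 0, cdG = 0),
                rimA = c(RimK = 1, RimA = 1, cdG = 0),
                cdG = c(RimK = 1, RimA = 0, cdG = 25),
                both = c(RimK = 1, RimA = 1, cdG = 25))
  rates <- vapply(conds, function(cc) {
    composite_rate(state_weights(m, cc, normalize = TRUE), 500)
  }, numeric(1))
  expect_lt(rates["basal"], rates["rimA"])
  expect_lt(rates["basal"], rates["cdG"])
  expect_lt(rates["rimA"], rates["both"])
  expect_lt(rates["cdG"], rates["both"])
})

test_that("Michaelis-Menten fit recovers noiseless truth and edge cases", {
  s <- c(50, 100, 250, 500, 1000, 2500, 5000)
  d <- rate_dataset("basal", s, 100 * s / (500 + s))
  fit <- michaelis_menten_fit(d)
  expect_equal(unname(fit["Vmax"]), 100, tolerance = 1e-6)
  expect_equal(unname(fit["Km"]), 500, tolerance = 1e-6)

  expect_warning(z <- michaelis_menten_fit(
    tibble::tibble(atp_uM = s, activity = rep(0, 7))), "zero")
  expect_equal(unname(z["Vmax"]), 0)

  expect_error(michaelis_menten_fit(
    tibble::tibble(atp_uM = rep(100, 5), activity = 1:5)), "distinct")
  expect_error(rate_dataset("x", c(100, 100, 200), c(1, 2, 3)), "distinct")
  expect_error(rate_dataset("x", c(0, 100, 200), c(1, 2, 3)), "> 0")
})

test_that("noisy replicate fits centre on the generating Km", {
  s <- c(50, 100, 250, 500, 1000, 2500, 5000)
  truth <- 100 * s / (500 + s)
  kms <- withr::with_seed(21, {
    vapply(seq_len(1000), function(i) {
      v <- pmax(0, truth * (1 + 0.05 * stats::rnorm(length(s))))
      fit <- tryCatch(michaelis_menten_fit(
        tibble::tibble(atp_uM = s, activity = v)),
        error = function(e) c(Vmax = NA_real_, Km = NA_real_))
      unname(fit["Km"])
    }, numeric(1))
  })
  expect_lt(abs(stats::median(kms, na.rm = TRUE) - 500) / 500, 0.10)
})

test_that("global fit is seed-deterministic", {
  dat <- gen_rate_data(assay_generator_config(noise = 0.02, seed = 3))
  f1 <- fit_model_params("four_state", dat, seed = 5,
                         control = list(generations = 15, pop_size = 20))
  f2 <- fit_model_params("four_state", dat, seed = 5,
                         control = list(generations = 15, pop_size = 20))
  expect_identical(f1$params, f2$params)
  expect_identical(f1$residual, f2$residual)
})

test_that("single-populated-state data reduces to the plain MM fit", {
  s <- c(50, 100, 250, 500, 1000, 2500, 5000)
  dat <- tibble::tibble(condition = "basal", atp_uM = s,
                        activity = 100 * s / (500 + s))
  f <- fit_model_params("two_state", dat,
                        conditions = list(basal = c(RimK = 1, RimA = 0,
                                                    cdG = 0)),
                        seed = 2, control = list(generations = 40))
  mm <- michaelis_menten_fit(dat)
  expect_equal(unname(f$params$kcat["basal"]), unname(mm["Vmax"]),
               tolerance = 1e-3)
  expect_equal(unname(f$params$Km["basal"]), unname(mm["Km"]),
               tolerance = 1e-3)
  # the unpopulated active state contributes nothing
  expect_equal(unname(f$params$kcat["active"]), 0)
})

test_that("fit validates conditions and bounds", {
  dat <- tibble::tibble(condition = "mystery", atp_uM = c(1, 2, 3),
                        activity = c(1, 2, 3))
  expect_error(fit_model_params("four_state", dat), "registry")
  dat2 <- tibble::tibble(condition = "basal", atp_uM = c(1, 2, 3),
                         activity = c(1, 2, 3))
  expect_error(
    fit_model_params("four_state", dat2,
                     conditions = list(basal = c(RimK = 1, RimA = 0, cdG = 0)),
                     bounds = list(Kd = c(10, 1))),
    "feasible")
})

test_that("model comparison orders by residual without significance claims", {
  dat <- gen_rate_data(assay_generator_config(noise = 0.02, seed = 8))
  ctl <- list(generations = 60, pop_size = 24)
  f4 <- fit_model_params("four_state", dat, seed = 4, control = ctl)
  f2 <- fit_model_params("two_state", dat, seed = 4, control = ctl)
  cmp <- compare_models(f2, f4)
  expect_equal(cmp$models$variant[1], "four_state")
  expect_gt(cmp$delta_residual, 0)

  same <- compare_models(f4, f4)
  expect_equal(same$delta_residual, 0)

  other <- gen_rate_data(assay_generator_config(noise = 0.02, seed = 9))
  f4b <- fit_model_params("four_state", other, seed = 4, control = ctl)
  expect_error(compare_models(f4, f4b), "identical datasets")
})

test_that("fit serializes to JSON with parameters, bounds and seed", {
  dat <- gen_rate_data(assay_generator_config(noise = 0, seed = 1))
  f <- fit_model_params("four_state", dat, seed = 1,
                        control = list(generations = 10, pop_size = 16))
  path <- tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$variant, "four_state")
  expect_equal(back$seed, 1)
  expect_equal(back$residual, f$residual, tolerance = 1e-12)
})
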