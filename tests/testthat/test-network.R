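test_that("network construction validates structure", {
  expect_error(
    reaction_network(c(R = 1, R = 2)),
    "unique")
  expect_error(
    reaction_network(c(R = -1)),
    "non-negative")
  expect_error(
    reaction_network(c(R = 1, RL = 0),
                     data.frame(a = "R", b = "L", complex = "RL", Kd_uM = 1)),
    "unknown species")
  expect_error(
    reaction_network(c(R = 1, L = 1, RL = 0),
                     data.frame(a = "R", b = "L", complex = "RL", Kd_uM = 0)),
    "Kd")
  # unreachable complex: formed only from another complex that never forms
  expect_error(
    reaction_network(c(R = 1, L = 1, X = 0, XL = 0),
                     data.frame(a = "X", b = "L", complex = "XL", Kd_uM = 1)),
    NA)  # X is elementary here, actually reachable
})

test_that("mass-action ODEs conserve moieties symbolically and numerically", {
  net <- pair_network()
  expect_true(all(moiety_balance(net) == 0L))
  m4 <- make_model("four_state")
  expect_true(all(moiety_balance(m4$network) == 0L))

  # zero-reaction network: derivative identically zero
  net0 <- reaction_network(c(A = 1, B = 2))
  rhs0 <- build_odes(net0)
  expect_equal(rhs0(0, c(A = 1, B = 2))[[1]], c(A = 0, B = 0))

  # numerical conservation over a long horizon for random valid networks
  for (seed in 1:4) {
    net <- random_cascade_network(seed)
    rhs <- build_odes(net)
    y0 <- stats::setNames(net$species$conc_uM, net$species$name)
    sol <- deSolve::ode(y = y0, times = c(0, 1e6), func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    yT <- sol[nrow(sol), -1]
    drift <- abs(moiety_totals(net, yT) - moiety_totals(net, y0)) /
      moiety_totals(net, y0)
    expect_lt(max(drift), 1e-8)
  }
})

test_that("integrated pair equilibrium matches the closed-form quadratic", {
  net <- pair_network(R = 2.5, L = 25, Kd = 1)
  ss <- solve_steady_state(net)
  exact <- pair_complex_exact(2.5, 25, 1)
  expect_equal(unname(ss["RL"]), exact, tolerance = 1e-6)
  expect_equal(unname(ss["RL"]), 2.3941, tolerance = 1e-4)
  expect_true(all(ss >= 0))
  expect_lt(attr(ss, "residual"), 1e-10)
  # moiety totals preserved
  tot <- moiety_totals(net, ss)
  expect_equal(unname(tot["R"]), 2.5, tolerance = 1e-9)
  expect_equal(unname(tot["L"]), 25, tolerance = 1e-9)
})

test_that("absent ligand leaves free receptor unchanged", {
  net <- pair_network(R = 2.5, L = 0, Kd = 1)
  ss <- solve_steady_state(net)
  expect_equal(unname(ss["RL"]), 0)
  expect_equal(unname(ss["R"]), 2.5)
})

test_that("ODE steady state equals direct equilibrium speciation", {
  # independent algebraic oracle vs integration, detailed-balanced networks
  for (seed in 1:5) {
    net <- random_cascade_network(seed + 10)
    a <- solve_steady_state(net, method = "ode")
    b <- solve_steady_state(net, method = "equilibrium")
    expect_equal(as.numeric(a), as.numeric(b), tolerance = 1e-6)
  }
})

test_that("thermodynamic cycle report flags inconsistent squares", {
  good <- check_thermodynamic_consistency(square_network())
  expect_equal(nrow(good), 1L)
  expect_true(good$pass[1])
  expect_true(attr(good, "consistent"))

  # perturb one Kd by exactly x2 while holding the closing Kd fixed
  bad <- check_thermodynamic_consistency(
    square_network(kd_a = 2, kd_a_on_kc = 1.5))
  expect_false(bad$pass[1])
  expect_equal(bad$kd_ratio[1], 2, tolerance = 1e-9)

  acyclic <- check_thermodynamic_consistency(pair_network())
  expect_equal(nrow(acyclic), 0L)
  expect_true(attr(acyclic, "consistent"))
})

test_that("pairwise bound fraction solves the exact quadratic", {
  expect_equal(pairwise_bound_fraction(2.5, 25, 1), 0.9576377,
               tolerance = 1e-6)
  expect_equal(round(100 * pairwise_bound_fraction(2.5, 25, 1)), 96)
  expect_equal(pairwise_bound_fraction(7, 0, 3), 0)
  expect_equal(pairwise_bound_fraction(1, 1, 1), (3 - sqrt(5)) / 2)
  expect_error(pairwise_bound_fraction(1, 1, 0), "Kd")
  expect_error(pairwise_bound_fraction(-1, 1, 1), "non-negative")
  # monotone increasing in ligand, decreasing in Kd
  lig <- pairwise_bound_fraction(2.5, seq(0, 50, by = 0.5), 1)
  expect_true(all(diff(lig) > 0))
  kds <- pairwise_bound_fraction(2.5, 25, 10^seq(-2, 2, by = 0.1))
  expect_true(all(diff(kds) < 0))
})

test_that("bound fraction agrees with the steady-state solver across draws", {
  withr::with_seed(99, {
    for (i in 1:100) {
      R <- runif(1, 0.1, 10)
      L <- runif(1, 0.1, 50)
      Kd <- 10^runif(1, -2, 2)
      ss <- solve_steady_state(pair_network(R, L, Kd), method = "equilibrium")
      expect_equal(unname(ss["RL"]) / R, pairwise_bound_fraction(R, L, Kd),
                   tolerance = 1e-6)
    }
    # the ODE route on a subsample
    for (i in 1:10) {
      R <- runif(1, 0.1, 10)
      L <- runif(1, 0.1, 50)
      Kd <- 10^runif(1, -2, 2)
      ss <- solve_steady_state(pair_network(R, L, Kd), method = "ode")
      expect_equal(unname(ss["RL"]) / R, pairwise_bound_fraction(R, L, Kd),
                   tolerance = 1e-6)
    }
  })
})

test_that("model variants have the declared state rosters and consistency", {
  m2 <- make_model("two_state")
  expect_equal(nrow(m2$states), 2L)
  m4 <- make_model("four_state")
  expect_equal(nrow(m4$states), 4L)
  expect_setequal(m4$states$state, c("apo", "rima", "cdg", "rima_cdg"))
  mb <- make_model("rimb_extended")
  expect_equal(nrow(mb$states), 5L)
  mt <- make_model("trigger")
  expect_true("RimA.cdG" %in% mt$network$species$name)
  expect_equal(mt$params$Kd_rima_cdg, 5)
  expect_equal(m4$params$Kd_rimk_cdg, 1)
  for (m in list(m2, m4, mb, mt)) {
    expect_true(attr(check_thermodynamic_consistency(m$network),
                     "consistent"))
  }
  expect_error(make_model("two_state", overrides = list(Kd_rima_cdg = 1)),
               "not present in variant")
})

test_that("trigger variant without RimB reduces to the four-state model", {
  wt <- state_weights(make_model("trigger", overrides = list(RimB = 0)))
  w4 <- state_weights(make_model("four_state"))
  expect_equal(wt$weight, w4$weight, tolerance = 1e-12)
  # with RimB present, cdG sequestration of RimA lowers the doubly-bound state
  wt1 <- state_weights(make_model("trigger"))
  expect_lt(wt1$weight[wt1$state == "rima_cdg"],
            w4$weight[w4$state == "rima_cdg"])
})

test_that("RimK moiety is fully accounted across activity states", {
  m <- make_model("four_state", overrides = list(cdG = 25))
  w <- state_weights(m)
  expect_equal(sum(w$weight), 1, tolerance = 1e-9)  # total RimK is 1 uM
  wn <- state_weights(m, normalize = TRUE)
  expect_equal(sum(wn$weight), 1, tolerance = 1e-9)
})

test_that("network YAML config and steady-state TSV round-trip", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c(
    "variant: pair",
    "species:",
    "  - {name: R, conc_uM: 2.5}",
    "  - {name: L, conc_uM: 25}",
    "  - {name: RL, conc_uM: 0}",
    "reactions:",
    "  - {a: R, b: L, complex: RL, Kd_uM: 1}"
  ), cfg)
  net <- read_network_config(cfg)
  expect_s3_class(net, "reaction_network")
  expect_equal(attr(net, "variant"), "pair")
  ss <- solve_steady_state(net, method = "equilibrium")
  out <- tempfile(fileext = ".tsv")
  write_steady_state_tsv(ss, out)
  back <- utils::read.delim(out)
  expect_equal(back$concentration_uM[back$species == "RL"],
               unname(ss["RL"]))
})
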