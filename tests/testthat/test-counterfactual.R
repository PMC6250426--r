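test_that("mean fitnesses at the boundaries use the endpoint profiles", {
  sys <- demo_systems()
  a <- sys$linear_low_assortment
  sel <- mean_fitnesses(a$u, a$fitness, p = 0)
  expect_equal(sel$S, -0.128)
  expect_equal(sel$mean_fitness_D, pi_D(a$fitness, 0))
  expect_equal(mean_fitnesses(a$ubar, a$fitness, p = 1)$S, -0.128)

  cc <- sys$quadratic_synergy
  expect_equal(mean_fitnesses(cc$u, cc$fitness, p = 0)$S, -0.33)
  expect_equal(mean_fitnesses(cc$ubar, cc$fitness, p = 1)$S, 0.45)

  # clonal mutant group: S(0) = piC(n) - piD(0)
  st1 <- make_structure("clonal_or_binomial", 10, list(r = 1))
  expect_equal(mean_fitnesses(st1, cc$fitness, 0)$S,
               pi_C(cc$fitness, 10) - pi_D(cc$fitness, 0))
  expect_error(mean_fitnesses(st1, demo_games()$synergy, 0), "mismatch")
})

test_that("invasion conditions are strict with closed-form thresholds", {
  g <- demo_games()$synergy
  # cooperators invade iff (1 - r) piC(1) + r piC(2) > piD(0), i.e.
  # r > 1.9 / 2.9
  st_hi <- make_structure("constant_r_2player", 2, list(r = 0.7))
  st_lo <- make_structure("constant_r_2player", 2, list(r = 0.5))
  inv <- can_invade(st_hi, g, "zero")
  expect_true(as.logical(inv))
  expect_equal(attr(inv, "lhs"), 0.3 * 0.1 + 0.7 * 3)
  expect_false(as.logical(can_invade(st_lo, g, "zero")))
  # lone mutant comparison at r = 0 with piC(1) < piD(0)
  st0 <- make_structure("constant_r_2player", 2, list(r = 0))
  expect_false(as.logical(can_invade(st0, g, "zero")))
  # an exact tie is neutral, reported as non-invasion
  r_star <- 1.9 / 2.9
  tie <- can_invade(make_structure("constant_r_2player", 2,
                                   list(r = r_star)), g, "zero")
  expect_false(as.logical(tie))
  expect_true(attr(tie, "neutral"))
})

test_that("relatedness is P(C|C) - P(C|D)", {
  # both constant-relatedness families return r at every p
  for (case in list(list(fam = "constant_r_2player", n = 2, r = 0.3),
                    list(fam = "clonal_or_binomial", n = 10, r = 0.45))) {
    st <- make_structure(case$fam, case$n, list(r = case$r))
    for (p in c(0, 0.1, 0.42, 0.9, 1))
      expect_equal(relatedness(st, p), case$r, tolerance = 1e-12)
  }
  # independence: well-mixed gives r = 0
  st0 <- make_structure("clonal_or_binomial", 6, list(r = 0))
  for (p in c(0, 0.3, 1)) expect_equal(relatedness(st0, p), 0)
  # profile route: r = (E[i] - 1) / (n - 1)
  expect_equal(relatedness(demo_systems()$linear_high_assortment$u, 0), 0.2)
})

test_that("population-level rb - c matches the endpoint inequality form", {
  sys <- demo_systems()
  a <- sys$linear_low_assortment
  cbr <- population_cb(a$u, a$fitness, 0)
  expect_equal(cbr$r, 0.04)
  expect_equal(cbr$b, 1.8)
  expect_equal(cbr$c, 0.2)
  expect_equal(cbr$hr, -0.128)
  expect_equal(hamilton_at_endpoint(a$u, a$fitness, "zero")$rb_minus_c,
               -0.128)
  b <- sys$linear_high_assortment
  expect_equal(population_cb(b$u, b$fitness, 0)$hr, 0.16)
  expect_equal(population_cb(b$ubar, b$fitness, 1)$hr, 0.16)

  # endpoint consistency holds for arbitrary fitness and profiles
  for (seed in 1:50) {
    n <- 2 + (seed %% 6)
    ff <- rand_fitness(n, seed)
    u <- rand_u_profile(n, seed + 1000)
    ub <- mirror_profile(rand_u_profile(n, seed + 2000))
    expect_equal(population_cb(u, ff, 0)$hr,
                 hamilton_at_endpoint(u, ff, "zero")$rb_minus_c,
                 tolerance = 1e-12)
    expect_equal(population_cb(ub, ff, 1)$hr,
                 hamilton_at_endpoint(ub, ff, "one")$rb_minus_c,
                 tolerance = 1e-12)
  }
})

test_that("Hamilton's rule can disagree with invasion for anti-synergies", {
  g <- demo_games()$antisynergy
  # violation window r in (1/29, 1/11): rb > c while invasion fails
  st <- make_structure("constant_r_2player", 2, list(r = 0.06))
  hr0 <- hamilton_at_endpoint(st, g, "zero")
  expect_equal(hr0$rb_minus_c, 0.06 * 2.9 - 0.1)
  expect_gt(hr0$rb_minus_c, 0)
  expect_false(as.logical(can_invade(st, g, "zero")))
  # outside the window the two agree
  st_in <- make_structure("constant_r_2player", 2, list(r = 0.2))
  expect_true(as.logical(can_invade(st_in, g, "zero")))
  expect_gt(hamilton_at_endpoint(st_in, g, "zero")$rb_minus_c, 0)
})

test_that("equal gains makes Hamilton's rule exact for any structure", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(2:8, 1)
    ff <- rand_equal_gains_fitness(n, seed)
    st <- generate_random_structure(seed, n = n, k_components = 2)
    # rb - c equals the selection differential at every p
    for (p in c(0, 0.25, 0.5, 0.75, 1)) {
      expect_equal(population_cb(st, ff, p)$hr,
                   mean_fitnesses(st, ff, p)$S, tolerance = 1e-10)
    }
    # the invasion condition and the endpoint inequality are literally the
    # same equation at both ends (identical left-hand sides)
    for (end in c("zero", "one")) {
      inv <- can_invade(st, ff, end)
      hae <- hamilton_at_endpoint(st, ff, end)
      gap <- attr(inv, "lhs") - attr(inv, "rhs")
      expect_equal(hae$lhs - hae$rhs, gap, tolerance = 1e-12)
    }
  }
})

test_that("synergy conditions classify the bundled systems correctly", {
  sys <- demo_systems()
  st <- make_structure("clonal_or_binomial", 10, list(r = 0.2))
  lin <- synergy_conditions(st, sys$linear_low_assortment$fitness)
  expect_true(lin$equal_gains)
  expect_identical(lin$verdict, "no_violation_possible")

  quad <- synergy_conditions(st, sys$quadratic_synergy$fitness)
  expect_false(quad$equal_gains)
  expect_true(quad$synergy_cond1)
  expect_true(quad$synergy_cond2)
  expect_true(quad$synergy_cond3)
  expect_identical(quad$verdict, "violations_only_out_of_equilibrium")

  st2 <- make_structure("constant_r_2player", 2, list(r = 0.3))
  anti <- synergy_conditions(st2, demo_games()$antisynergy)
  expect_false(anti$synergy_cond1)  # piC(2) = 3 < 1.9 + 2.9
  expect_identical(anti$verdict, "in_equilibrium_violations_possible")
  expect_error(synergy_conditions(st2, demo_games()$antisynergy,
                                  grid_size = 5), "at least 11")
})

test_that("the engine matches the affine closed form for 2-player games", {
  for (g in demo_games()) {
    for (r in c(0, 0.25, 0.5, 0.9)) {
      st <- make_structure("constant_r_2player", 2, list(r = r))
      ab <- affine_S_oracle(g, r)
      for (p in c(0, 0.2, 0.5, 0.8, 1)) {
        expect_equal(mean_fitnesses(st, g, p)$S,
                     unname(ab["intercept"] + ab["slope"] * p),
                     tolerance = 1e-12)
      }
    }
  }
})
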