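test_that("built-in families satisfy the consistency constraints", {
  cases <- list(
    make_structure("constant_r_2player", 2, list(r = 0.3)),
    make_structure("clonal_or_binomial", 10, list(r = 0.2)),
    make_structure("clonal_or_binomial", 4, list(r = 0)),
    make_structure("clonal_or_binomial", 4, list(r = 1)))
  for (st in cases) {
    rep <- validate_structure(st, grid_size = 101)
    expect_true(rep$passed)
    expect_lt(rep$max_sum_dev, 1e-12)
    expect_lt(rep$max_mean_dev, 1e-12)
    expect_lt(rep$max_negativity, 1e-12)
  }
})

test_that("validation catches broken and non-finite structures", {
  base <- make_structure("constant_r_2player", 2, list(r = 0.3))
  broken <- make_structure("custom", 2, list(f = function(p) {
    fv <- base$f(p)
    fv[2] <- fv[2] * 1.01
    fv
  }))
  rep <- validate_structure(broken, grid_size = 51)
  expect_false(rep$passed)
  expect_gt(rep$max_sum_dev, 1e-4)
  bad <- make_structure("custom", 2, list(f = function(p) c(NaN, 0, 1)))
  expect_error(validate_structure(bad), "non-finite")
  expect_error(validate_structure(base, grid_size = 2), "at least 3")
})

test_that("endpoint profiles of the constant-relatedness families", {
  st <- make_structure("constant_r_2player", 2, list(r = 0.3))
  pr <- profiles_from_structure(st)
  expect_equal(unname(pr$u$weights), c(0, 0.7, 0.3))
  expect_equal(unname(pr$ubar$weights), c(0.3, 0.7, 0))

  # full assortment: a mutant cooperator is always with its clone
  st1 <- make_structure("constant_r_2player", 2, list(r = 1))
  expect_equal(unname(profiles_from_structure(st1)$u$weights), c(0, 0, 1))

  # clonal-or-binomial: rare cooperator is alone (prob 1 - r) or in an
  # all-cooperator clonal group (prob r)
  st10 <- make_structure("clonal_or_binomial", 10, list(r = 0.2))
  u <- profiles_from_structure(st10)$u$weights
  expect_equal(unname(u[2]), 0.8)
  expect_equal(unname(u[11]), 0.2)
  expect_equal(sum(u), 1)
})

test_that("numerical limit path agrees with the analytic profiles", {
  for (case in list(list(n = 2, r = 0.3), list(n = 10, r = 0.37))) {
    ana <- make_structure("clonal_or_binomial", case$n, list(r = case$r))
    num <- make_structure("custom", case$n, list(f = ana$f))
    expect_null(num$endpoints)
    pn <- profiles_from_structure(num)
    pa <- profiles_from_structure(ana)
    expect_lt(max(abs(pn$u$weights - pa$u$weights)), 1e-6)
    expect_lt(max(abs(pn$ubar$weights - pa$ubar$weights)), 1e-6)
    expect_identical(unname(pn$u$weights[1]), 0)
    expect_identical(unname(pn$ubar$weights[case$n + 1]), 0)
  }
  # a structure violating one-sided differentiability fails loudly
  rough <- make_structure("custom", 2, list(f = function(p)
    c(1 - p - sin(1 / max(p, 1e-30)) * p * 0.1,
      sin(1 / max(p, 1e-30)) * p * 0.1 + 0 * p, p)))
  expect_error(profiles_from_structure(rough), "converge|differentiable")
})

test_that("interior conditional distributions match direct evaluation", {
  st <- make_structure("constant_r_2player", 2, list(r = 0.3))
  v <- conditional_distributions(st, 0.5)
  expect_equal(unname(v$vC$weights), c(0, 0.35, 0.65))
  # well-mixed: partner is a cooperator with probability p
  st0 <- make_structure("constant_r_2player", 2, list(r = 0))
  expect_equal(unname(conditional_distributions(st0, 0.5)$vC$weights),
               c(0, 0.5, 0.5))
  # vC converges to u as p -> 0
  u <- profiles_from_structure(st)$u$weights
  vC_small <- conditional_distributions(st, 1e-8)$vC$weights
  expect_lt(max(abs(vC_small - u)), 1e-7)
  expect_error(conditional_distributions(st, 0), "strictly inside")
  expect_error(conditional_distributions(st, 1), "strictly inside")
})

test_that("constant_r_2player evaluates to its closed form", {
  st <- make_structure("constant_r_2player", 2, list(r = 0))
  expect_equal(st$f(0.5)[2], 0.5)  # well-mixed heterozygote-like share
  st3 <- make_structure("constant_r_2player", 2, list(r = 0.3))
  expect_equal(st3$f(0.5), c(0.325, 0.35, 0.325))
  expect_error(make_structure("constant_r_2player", 3, list(r = 0.3)),
               "n = 2")
  expect_error(make_structure("constant_r_2player", 2, list(r = 1.2)),
               "\\[0, 1\\]")
})

test_that("mixtures are valid and their profiles combine linearly", {
  comps <- list(make_structure("constant_r_2player", 2, list(r = 0)),
                make_structure("constant_r_2player", 2, list(r = 1)))
  mix <- make_structure("mixture", 2,
                        list(components = comps, weights = c(0.7, 0.3)))
  expect_true(validate_structure(mix)$passed)
  expect_equal(unname(profiles_from_structure(mix)$u$weights),
               c(0, 0.7, 0.3))
  # random mixtures: profile of the mixture = mixture of the profiles
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:6, 1)
    k <- sample(2:4, 1)
    rs <- runif(k)
    w <- runif(k); w <- w / sum(w)
    parts <- lapply(rs, function(r)
      make_structure("clonal_or_binomial", n, list(r = r)))
    mix <- make_structure("mixture", n,
                          list(components = parts, weights = w))
    expect_true(validate_structure(mix, grid_size = 21)$passed)
    pm <- profiles_from_structure(mix)
    ucombo <- Reduce(`+`, Map(function(s, wt)
      wt * profiles_from_structure(s)$u$weights, parts, w))
    expect_equal(unname(pm$u$weights), unname(ucombo), tolerance = 1e-12)
  }
  expect_error(make_structure("mixture", 2, list(components = comps,
                                                 weights = c(0.7, 0.4))),
               "simplex")
})

test_that("endpoint_profiles structures reproduce the requested profiles", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:8, 1)
    wu <- rexp(n); wu <- wu / sum(wu)
    wb <- rexp(n); wb <- wb / sum(wb)
    st <- make_structure("endpoint_profiles", n,
                         list(u = c(0, wu), ubar = c(wb, 0)))
    expect_true(validate_structure(st, grid_size = 51)$passed)
    pr <- profiles_from_structure(st)
    expect_equal(unname(pr$u$weights), c(0, wu))
    expect_equal(unname(pr$ubar$weights), c(wb, 0))
    # the numerical limit of f itself agrees with the requested u
    num <- make_structure("custom", n, list(f = st$f))
    expect_lt(max(abs(profiles_from_structure(num)$u$weights - c(0, wu))),
              1e-6)
  }
  expect_error(make_structure("endpoint_profiles", 3,
                              list(u = c(0.2, 0.3, 0.5, 0),
                                   ubar = c(0.5, 0.5, 0, 0))),
               "at least one cooperator")
  expect_error(make_structure("endpoint_profiles", 3,
                              list(u = c(0, 0.4, 0.4, 0.4),
                                   ubar = c(1, 0, 0, 0))),
               "sum to 1")
})

test_that("random structures are reproducible and always valid", {
  a <- generate_random_structure(seed = 1, n = 2, k_components = 3)
  b <- generate_random_structure(seed = 1, n = 2, k_components = 3)
  ps <- seq(0, 1, length.out = 11)
  expect_equal(lapply(ps, a$f), lapply(ps, b$f))
  for (seed in c(2, 5, 9)) {
    st <- generate_random_structure(seed, n = 10, k_components = 2)
    expect_true(validate_structure(st, grid_size = 31)$passed)
    pr <- profiles_from_structure(st)
    expect_equal(sum(pr$u$weights), 1)
    expect_equal(sum(pr$ubar$weights), 1)
  }
})

test_that("structure JSON specs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"family": "mixture", "n": 2, "params": {
    "weights": [0.6, 0.4],
    "components": [
      {"family": "constant_r_2player", "n": 2, "params": {"r": 0.2}},
      {"family": "constant_r_2player", "n": 2, "params": {"r": 0.9}}]}}',
    path)
  st <- read_structure_json(path)
  expect_true(validate_structure(st)$passed)
  expect_equal(unname(profiles_from_structure(st)$u$weights),
               c(0, 0.6 * 0.8 + 0.4 * 0.1, 0.6 * 0.2 + 0.4 * 0.9))
})

test_that("bundled example profiles have the documented moments", {
  sys <- demo_systems()
  expect_equal(profile_moment(sys$linear_low_assortment$u), 1.36)
  expect_equal(relatedness(sys$linear_high_assortment$u, p = 0), 0.2)
  expect_equal(profile_moment(sys$quadratic_synergy$u, power = 2), 8.5)
  # every bundled ubar is the mirror image of its u
  for (nm in c("linear_low_assortment", "linear_high_assortment",
               "quadratic_synergy")) {
    expect_equal(unname(sys[[nm]]$ubar$weights),
                 rev(unname(sys[[nm]]$u$weights)))
  }
  expect_error(mirror_profile(
    conditional_distributions(
      make_structure("constant_r_2player", 2, list(r = 0.3)), 0.4)$vC),
    "endpoint")
})
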