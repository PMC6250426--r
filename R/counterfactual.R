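#' @title Counterfactual engine
#' @description Direction of selection, counterfactual costs and benefits,
#'   relatedness, Hamilton's rule and its violations for a fitness function
#'   combined with a population structure.
#' @name counterfactual-engine
NULL

# Resolve the endpoint profile (u or ubar) from either a structure or a
# profile supplied directly.
endpoint_profile_of <- function(x, end, ctrl = hr_control()) {
  if (inherits(x, "hr_profile")) {
    if (x$end != end)
      stop("profile supplied for end = '", x$end, "' but end = '", end,
           "' was requested")
    return(x)
  }
  if (!inherits(x, "hr_structure"))
    stop("expected an hr_structure or an endpoint hr_profile")
  pr <- profiles_from_structure(x, ctrl)
  if (end == "zero") pr$u else pr$ubar
}

check_dims <- function(x, fitness) {
  if (!inherits(fitness, "hr_fitness"))
    stop("expected an hr_fitness object")
  if (x$n != fitness$n)
    stop("group size mismatch: structure/profile has n = ", x$n,
         " but fitness has n = ", fitness$n)
}

#' Mean fitness of cooperators and defectors
#'
#' At p = 0 the average mutant cooperator experiences group compositions
#' distributed as the profile u, while every defector is in an all-defector
#' group; at p = 1 the roles reverse with ubar.  At interior p the averages
#' are taken over the conditional composition distributions of each type.
#' The selection differential \eqn{S(p) = \bar\pi_C(p) - \bar\pi_D(p)}
#' determines the direction of selection exactly.
#'
#' @param x An `"hr_structure"`, or (for `p` equal to 0 or 1) an endpoint
#'   `"hr_profile"`.
#' @param fitness An [fitness_function()].
#' @param p Overall cooperator frequency in \[0, 1\].
#' @param ctrl An [hr_control()] object.
#' @return A list of class `"hr_selection"`: `p`, `mean_fitness_C`,
#'   `mean_fitness_D`, `S`.
#' @export
mean_fitnesses <- function(x, fitness, p, ctrl = hr_control()) {
  check_dims(x, fitness)
  n <- fitness$n
  if (p == 0) {
    u <- endpoint_profile_of(x, "zero", ctrl)
    mC <- sum(u$weights[-1L] * pi_C(fitness, 1:n))
    mD <- pi_D(fitness, 0L)
  } else if (p == 1) {
    ub <- endpoint_profile_of(x, "one", ctrl)
    mC <- pi_C(fitness, n)
    mD <- sum(ub$weights[-(n + 1L)] * pi_D(fitness, 0:(n - 1L)))
  } else {
    v <- conditional_distributions(x, p, ctrl)
    mC <- sum(v$vC$weights[-1L] * pi_C(fitness, 1:n))
    mD <- sum(v$vD$weights[-(n + 1L)] * pi_D(fitness, 0:(n - 1L)))
  }
  structure(list(p = p, mean_fitness_C = mC, mean_fitness_D = mD,
                 S = mC - mD), class = "hr_selection")
}

#' @export
print.hr_selection <- function(x, ...) {
  cat(sprintf("p = %g: mean fitness C = %.6g, D = %.6g, S = C - D = %.6g\n",
              x$p, x$mean_fitness_C, x$mean_fitness_D, x$S))
  invisible(x)
}

#' Invasion analysis at the boundaries
#'
#' Cooperators invade a defector population when their average fitness at
#' p = 0 exceeds \eqn{\pi_D(0)}; defectors invade a cooperator population
#' when their average fitness at p = 1 exceeds \eqn{\pi_C(n)}.  Invasion
#' requires a strict inequality; exact ties are reported as non-invasion
#' with the `"neutral"` attribute set.
#'
#' @inheritParams mean_fitnesses
#' @param end `"zero"` (can cooperators invade?) or `"one"` (can defectors
#'   invade?).
#' @return Logical scalar with attributes `neutral`, `lhs` (invader mean
#'   fitness) and `rhs` (resident fitness).
#' @export
can_invade <- function(x, fitness, end = c("zero", "one"),
                       ctrl = hr_control()) {
  end <- match.arg(end)
  check_dims(x, fitness)
  sel <- mean_fitnesses(x, fitness, p = if (end == "zero") 0 else 1, ctrl)
  if (end == "zero") {
    lhs <- sel$mean_fitness_C
    rhs <- sel$mean_fitness_D
  } else {
    lhs <- sel$mean_fitness_D
    rhs <- sel$mean_fitness_C
  }
  neutral <- abs(lhs - rhs) <= 64 * .Machine$double.eps *
    max(1, abs(lhs), abs(rhs))
  out <- !neutral && lhs > rhs
  attr(out, "neutral") <- neutral
  attr(out, "lhs") <- lhs
  attr(out, "rhs") <- rhs
  out
}

#' Relatedness r = P(C|C) - P(C|D)
#'
#' Relatedness is the excess probability that a randomly chosen group mate
#' of a cooperator is itself a cooperator, relative to the same probability
#' for a defector's group mate: \eqn{P(C|C) = \sum_i v^C_i (i-1)/(n-1)} and
#' \eqn{P(C|D) = \sum_i v^D_i \, i/(n-1)}.  At p = 0 defectors have no
#' cooperating partners, so r reduces to \eqn{\sum_i u_i (i-1)/(n-1)}; at
#' p = 1 cooperators only meet cooperators and
#' \eqn{r = 1 - \sum_i \bar u_i \, i/(n-1)}.
#'
#' @inheritParams mean_fitnesses
#' @return Relatedness, a dimensionless number in \[-1, 1\].
#' @export
relatedness <- function(x, p, ctrl = hr_control()) {
  n <- x$n
  if (n < 2L) stop("relatedness is undefined for groups of size 1")
  if (p == 0) {
    u <- endpoint_profile_of(x, "zero", ctrl)
    unname(sum(u$weights * ((0:n) - 1) / (n - 1)) +
             u$weights[1L] / (n - 1))
  } else if (p == 1) {
    ub <- endpoint_profile_of(x, "one", ctrl)
    1 - sum(ub$weights * (0:n) / (n - 1))
  } else {
    v <- conditional_distributions(x, p, ctrl)
    pCC <- sum(v$vC$weights * ((0:n) - 1) / (n - 1)) +
      v$vC$weights[1L] / (n - 1)
    pCD <- sum(v$vD$weights * (0:n) / (n - 1))
    unname(pCC - pCD)
  }
}

#' Counterfactual cost and benefit at a given group composition
#'
#' For a focal cooperator in a group with `i` cooperators (itself included),
#' the counterfactual cost is what it would gain by switching to defection,
#' \eqn{c_i = \pi_D(i-1) - \pi_C(i)}; the aggregate benefit is the total
#' fitness change its cooperation causes in the other n - 1 group members,
#' \eqn{b_i = (i-1)[\pi_C(i) - \pi_C(i-1)] + (n-i)[\pi_D(i) - \pi_D(i-1)]}.
#' At i = 1 this reduces to \eqn{b_1 = (n-1)[\pi_D(1) - \pi_D(0)]} and
#' \eqn{c_1 = \pi_D(0) - \pi_C(1)}; at i = n to
#' \eqn{b_n = (n-1)[\pi_C(n) - \pi_C(n-1)]} and
#' \eqn{c_n = \pi_D(n-1) - \pi_C(n)}.
#'
#' @param fitness An [fitness_function()].
#' @param i Composition(s), integer(s) in 1..n.
#' @return A data.frame with columns `i`, `c`, `b`.
#' @export
counterfactual_cb <- function(fitness, i) {
  stopifnot(inherits(fitness, "hr_fitness"))
  i <- as.integer(i)
  if (any(i < 1L | i > fitness$n))
    stop("composition i must lie in 1..n for a focal cooperator")
  n <- fitness$n
  cc <- pi_D(fitness, i - 1L) - pi_C(fitness, i)
  b <- numeric(length(i))
  hi <- i > 1L
  if (any(hi))
    b[hi] <- (i[hi] - 1L) * (pi_C(fitness, i[hi]) - pi_C(fitness, i[hi] - 1L))
  lo <- i < n
  if (any(lo))
    b[lo] <- b[lo] +
      (n - i[lo]) * (pi_D(fitness, i[lo]) - pi_D(fitness, i[lo] - 1L))
  data.frame(i = i, c = cc, b = b)
}

#' Population-level counterfactual cost, benefit, relatedness and rb - c
#'
#' Combines counterfactual costs and benefits with relatedness at the same
#' frequency and reports Hamilton's rule value \eqn{hr = r\,b - c}.
#'
#' At the boundaries the relevant counterfactual is the switch of a focal in
#' the resident group type: at p = 0 the residents form all-defector
#' groups, so \eqn{c = \pi_D(0) - \pi_C(1)} and
#' \eqn{b = (n-1)[\pi_D(1) - \pi_D(0)]} (the composition-1 switch values);
#' at p = 1 symmetrically \eqn{c = \pi_D(n-1) - \pi_C(n)},
#' \eqn{b = (n-1)[\pi_C(n) - \pi_C(n-1)]}.  With these, rb - c agrees with
#' the endpoint inequality form of Hamilton's rule
#' ([hamilton_at_endpoint()]) to machine precision for every fitness
#' function and profile.  At interior p, where no single resident group
#' type exists, `c(p)` and `b(p)` are the expectations of the
#' per-composition values \eqn{c_i, b_i} over the cooperators' conditional
#' composition distribution — an averaging contract isolated here; note
#' that for non-linear fitness functions its \eqn{p \to 0} limit need not
#' equal the boundary value.
#'
#' @inheritParams mean_fitnesses
#' @return A list of class `"hr_cbr"`: `p`, `r`, `c`, `b`, `hr`
#'   (`hr == r * b - c` exactly as stored).
#' @export
population_cb <- function(x, fitness, p, ctrl = hr_control()) {
  check_dims(x, fitness)
  n <- fitness$n
  if (p == 0) {
    cb <- counterfactual_cb(fitness, 1L)
    cbar <- cb$c
    bbar <- cb$b
  } else if (p == 1) {
    cb <- counterfactual_cb(fitness, n)
    cbar <- cb$c
    bbar <- cb$b
  } else {
    w <- conditional_distributions(x, p, ctrl)$vC$weights[-1L]
    cb <- counterfactual_cb(fitness, 1:n)
    cbar <- sum(w * cb$c)
    bbar <- sum(w * cb$b)
  }
  r <- relatedness(x, p, ctrl)
  structure(list(p = p, r = r, c = cbar, b = bbar, hr = r * bbar - cbar),
            class = "hr_cbr")
}

#' @export
print.hr_cbr <- function(x, ...) {
  cat(sprintf("p = %g: r = %.6g, c = %.6g, b = %.6g, rb - c = %.6g\n",
              x$p, x$r, x$c, x$b, x$hr))
  invisible(x)
}

#' Hamilton's rule rewritten as an endpoint inequality
#'
#' At p = 0, Hamilton's rule rb > c is equivalent to
#' \deqn{\sum_i u_i \{\pi_C(1) + (i-1)[\pi_D(1) - \pi_D(0)]\} > \pi_D(0),}
#' which substitutes for the invasion condition the fitness a cooperator
#' would have if payoffs grew linearly at the rate set by the first
#' cooperator.  At p = 1 the mirrored inequality
#' \deqn{\sum_i \bar u_i \{\pi_D(n-1) - (n-i-1)[\pi_C(n) - \pi_C(n-1)]\} >
#' \pi_C(n)} is equivalent to rb < c.  The report carries both sides and the
#' implied rb - c value, which agrees with [population_cb()] to machine
#' precision.
#'
#' @inheritParams can_invade
#' @return A list of class `"hr_endpoint"`: `end`, `lhs`, `rhs`, `holds`
#'   (lhs > rhs), `rb_minus_c`.
#' @export
hamilton_at_endpoint <- function(x, fitness, end = c("zero", "one"),
                                 ctrl = hr_control()) {
  end <- match.arg(end)
  check_dims(x, fitness)
  n <- fitness$n
  if (end == "zero") {
    u <- endpoint_profile_of(x, "zero", ctrl)$weights
    d <- pi_D(fitness, 1L) - pi_D(fitness, 0L)
    lhs <- sum(u[-1L] * (pi_C(fitness, 1L) + ((1:n) - 1) * d))
    rhs <- pi_D(fitness, 0L)
    rb_minus_c <- lhs - rhs
  } else {
    ub <- endpoint_profile_of(x, "one", ctrl)$weights
    d <- pi_C(fitness, n) - pi_C(fitness, n - 1L)
    lhs <- sum(ub[-(n + 1L)] *
                 (pi_D(fitness, n - 1L) - (n - (0:(n - 1L)) - 1) * d))
    rhs <- pi_C(fitness, n)
    rb_minus_c <- rhs - lhs  # lhs > rhs is equivalent to rb < c
  }
  structure(list(end = end, lhs = lhs, rhs = rhs, holds = lhs > rhs,
                 rb_minus_c = rb_minus_c), class = "hr_endpoint")
}

#' @export
print.hr_endpoint <- function(x, ...) {
  cat(sprintf(
    "Hamilton's rule at p = %s: lhs = %.6g, rhs = %.6g, rb - c = %.6g\n",
    if (x$end == "zero") "0" else "1", x$lhs, x$rhs, x$rb_minus_c))
  invisible(x)
}

#' Synergy conditions and violation road map
#'
#' Classifies a fitness function / population structure pair by the three
#' synergy conditions that preclude in-equilibrium violations of Hamilton's
#' rule:
#'
#' 1. \eqn{\pi_C(i) \ge \pi_C(1) + (i-1)[\pi_D(1) - \pi_D(0)]} for all i,
#' 2. \eqn{\pi_D(i) \ge \pi_D(n-1) - (n-i-1)[\pi_C(n) - \pi_C(n-1)]} for
#'    all i,
#' 3. the selection differential \eqn{S(p)} is nondecreasing in p (checked
#'    on a grid).
#'
#' When conditions 1 and 2 hold with equality everywhere the system has
#' equal gains from switching and Hamilton's rule can never disagree with
#' selection.  When all three hold, violations can only occur out of
#' equilibrium (selection moves the population out of any disagreement
#' region).  Otherwise in-equilibrium violations are possible, typically at
#' mixed equilibria created by anti-synergies.
#'
#' @inheritParams mean_fitnesses
#' @param grid_size Number of p-grid points for the monotonicity check
#'   (at least 11).
#' @return A list of class `"hr_classification"`: `equal_gains`,
#'   `synergy_cond1`, `synergy_cond2`, `synergy_cond3`, `verdict`.
#' @export
synergy_conditions <- function(x, fitness, grid_size = 101L,
                               ctrl = hr_control()) {
  check_dims(x, fitness)
  if (grid_size < 11L) stop("grid_size must be at least 11")
  n <- fitness$n
  tol <- ctrl$equal_gains_tol
  d0 <- pi_D(fitness, 1L) - pi_D(fitness, 0L)
  gap1 <- pi_C(fitness, 1:n) - (pi_C(fitness, 1L) + ((1:n) - 1) * d0)
  d1 <- pi_C(fitness, n) - pi_C(fitness, n - 1L)
  gap2 <- pi_D(fitness, 0:(n - 1L)) -
    (pi_D(fitness, n - 1L) - (n - (0:(n - 1L)) - 1) * d1)
  cond1 <- all(gap1 >= -tol)
  cond2 <- all(gap2 >= -tol)
  equal_gains <- all(abs(gap1) <= tol) && all(abs(gap2) <= tol)
  ps <- seq(0, 1, length.out = grid_size)
  S <- vapply(ps, function(p) mean_fitnesses(x, fitness, p, ctrl)$S, 0)
  cond3 <- all(diff(S) >= -tol)
  verdict <- if (equal_gains) "no_violation_possible"
  else if (cond1 && cond2 && cond3) "violations_only_out_of_equilibrium"
  else "in_equilibrium_violations_possible"
  structure(list(equal_gains = equal_gains, synergy_cond1 = cond1,
                 synergy_cond2 = cond2, synergy_cond3 = cond3,
                 verdict = verdict), class = "hr_classification")
}

#' @export
print.hr_classification <- function(x, ...) {
  cat(sprintf(paste0("System classification:\n  equal gains: %s\n",
                     "  synergy conditions: %s %s %s\n  verdict: %s\n"),
              x$equal_gains, x$synergy_cond1, x$synergy_cond2,
              x$synergy_cond3, x$verdict))
  invisible(x)
}

#' Locate equilibria of the cooperator-frequency dynamics
#'
#' Scans the selection differential S(p) for sign changes on an interior
#' grid, refines each root by bisection until \eqn{|S(p^*)| <} `tol`,
#' classifies stability from the sign of S on either side (positive below
#' and negative above the root means stable), classifies the endpoints by
#' invasion analysis, and evaluates Hamilton's rule rb - c at every interior
#' equilibrium.
#'
#' @inheritParams mean_fitnesses
#' @param grid_size Scan grid resolution (at least 101).
#' @param tol Root tolerance on |S|; defaults to `ctrl$root_tol`.
#' @return A list of class `"hr_equilibria"`: `interior` (data.frame with
#'   columns `p_star`, `stability`, `S`, `hr`), `p0`/`p1` endpoint reports,
#'   `degenerate` flag.
#' @export
find_equilibria <- function(x, fitness, grid_size = 1001L, tol = NULL,
                            ctrl = hr_control()) {
  check_dims(x, fitness)
  if (grid_size < 101L) stop("grid_size must be at least 101")
  if (is.null(tol)) tol <- ctrl$root_tol
  S_of <- function(p) mean_fitnesses(x, fitness, p, ctrl)$S
  ps <- seq(0, 1, length.out = grid_size)
  S <- vapply(ps, S_of, 0)
  degenerate <- all(abs(S) < 1e-12)
  if (degenerate)
    warning("selection differential is identically ~0; no roots reported")
  roots <- numeric(0)
  if (!degenerate) {
    interior <- 2:(grid_size - 1L)
    # grid nodes that are themselves (numerical) roots
    node_roots <- ps[interior][abs(S[interior]) <= tol]
    sgn <- sign(S)
    for (k in seq_len(grid_size - 1L)) {
      if (sgn[k] != 0 && sgn[k + 1L] != 0 && sgn[k] != sgn[k + 1L]) {
        lo <- ps[k]; hi <- ps[k + 1L]
        flo <- S[k]
        for (iter in 1:200) {
          mid <- (lo + hi) / 2
          fm <- S_of(mid)
          if (abs(fm) < tol || (hi - lo) < 1e-15) break
          if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
        }
        roots <- c(roots, (lo + hi) / 2)
      }
    }
    roots <- sort(unique(c(roots, node_roots)))
    roots <- roots[roots > 1e-12 & roots < 1 - 1e-12]
    if (length(roots) > 1)
      roots <- roots[c(TRUE, diff(roots) > 2 / grid_size)]
  }
  h <- 0.5 / grid_size
  interior_df <- data.frame(p_star = numeric(0), stability = character(0),
                            S = numeric(0), hr = numeric(0))
  for (p_star in roots) {
    s_lo <- S_of(max(p_star - h, 1e-12))
    s_hi <- S_of(min(p_star + h, 1 - 1e-12))
    stab <- if (s_lo > 0 && s_hi < 0) "stable" else "unstable"
    interior_df <- rbind(interior_df, data.frame(
      p_star = p_star, stability = stab, S = S_of(p_star),
      hr = population_cb(x, fitness, p_star, ctrl)$hr))
  }
  inv0 <- can_invade(x, fitness, "zero", ctrl)
  inv1 <- can_invade(x, fitness, "one", ctrl)
  structure(list(
    interior = interior_df,
    p0 = list(cooperators_invade = as.logical(inv0),
              stable = !as.logical(inv0), hr = population_cb(
                x, fitness, 0, ctrl)$hr),
    p1 = list(defectors_invade = as.logical(inv1),
              stable = !as.logical(inv1), hr = population_cb(
                x, fitness, 1, ctrl)$hr),
    degenerate = degenerate), class = "hr_equilibria")
}

#' @export
print.hr_equilibria <- function(x, ...) {
  cat("Equilibria:\n")
  cat(sprintf("  p = 0: %s (cooperators %s invade), rb - c = %.6g\n",
              if (x$p0$stable) "stable" else "unstable",
              if (x$p0$cooperators_invade) "can" else "cannot", x$p0$hr))
  if (nrow(x$interior) == 0) cat("  no interior equilibria\n")
  else for (k in seq_len(nrow(x$interior)))
    cat(sprintf("  p* = %.6g (%s), S = %.3g, rb - c = %.6g\n",
                x$interior$p_star[k], x$interior$stability[k],
                x$interior$S[k], x$interior$hr[k]))
  cat(sprintf("  p = 1: %s (defectors %s invade), rb - c = %.6g\n",
              if (x$p1$stable) "stable" else "unstable",
              if (x$p1$defectors_invade) "can" else "cannot", x$p1$hr))
  invisible(x)
}

#' Map disagreement between Hamilton's rule and the direction of selection
#'
#' Tabulates S(p) and rb - c over a frequency grid, flags where their signs
#' agree, lists the maximal disagreement intervals, and reports whether any
#' stable state (interior equilibrium or uninvadable endpoint) lies inside a
#' disagreement region — an in-equilibrium violation of Hamilton's rule.
#'
#' @inheritParams mean_fitnesses
#' @param grid_size Grid resolution.
#' @return A list of class `"hr_violation_map"`: `table` (data.frame with
#'   columns `p`, `S`, `hr`, `r`, `c`, `b`, `agree`), `disagreement`
#'   (data.frame of interval endpoints), `in_equilibrium_violation`,
#'   `equilibria`.
#' @export
violation_map <- function(x, fitness, grid_size = 201L,
                          ctrl = hr_control()) {
  check_dims(x, fitness)
  ps <- seq(0, 1, length.out = grid_size)
  rows <- lapply(ps, function(p) {
    sel <- mean_fitnesses(x, fitness, p, ctrl)
    cbr <- population_cb(x, fitness, p, ctrl)
    data.frame(p = p, S = sel$S, hr = cbr$hr, r = cbr$r, c = cbr$c,
               b = cbr$b)
  })
  tab <- do.call(rbind, rows)
  tab$agree <- sign_tol(tab$S, ctrl$violation_tol) ==
    sign_tol(tab$hr, ctrl$violation_tol)
  runs <- rle(!tab$agree)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  dis <- data.frame(p_lo = ps[starts[runs$values]],
                    p_hi = ps[ends[runs$values]])
  eq <- find_equilibria(x, fitness, grid_size = max(1001L, grid_size),
                        ctrl = ctrl)
  # only *stable* states count: at an unstable boundary selection carries
  # the population away from the disagreement, which is precisely why such
  # violations cannot be observed in equilibrium
  viol <- FALSE
  if (nrow(eq$interior) > 0) {
    st <- eq$interior[eq$interior$stability == "stable", ]
    viol <- any(abs(st$hr) > ctrl$violation_tol)
  }
  if (eq$p0$stable && eq$p0$hr > ctrl$violation_tol) viol <- TRUE
  if (eq$p1$stable && eq$p1$hr < -ctrl$violation_tol) viol <- TRUE
  structure(list(table = tab, disagreement = dis,
                 in_equilibrium_violation = viol, equilibria = eq),
            class = "hr_violation_map")
}

#' @export
print.hr_violation_map <- function(x, ...) {
  cat(sprintf(paste0("Violation map over %d frequencies: %d disagreement ",
                     "interval(s); in-equilibrium violation: %s\n"),
              nrow(x$table), nrow(x$disagreement),
              x$in_equilibrium_violation))
  invisible(x)
}

#' Scan a 2-player game over relatedness and frequency
#'
#' For each r in `r_grid`, builds the constant-relatedness 2-player
#' structure and evaluates the selection differential and Hamilton's rule
#' over `p_grid`, producing the region data (where cooperation is selected
#' for versus where inclusive fitness is positive).
#'
#' @param game An `"hr_fitness"` with n = 2 (see [game_matrix()]).
#' @param r_grid,p_grid Numeric grids in \[0, 1\].
#' @param ctrl An [hr_control()] object.
#' @return A data.frame with columns `p`, `S`, `hr`, `r`, `c`, `b`, `agree`
#'   (one row per (r, p) pair; `r` is the constant relatedness of the row's
#'   structure).
#' @export
scan_constant_r <- function(game, r_grid = seq(0, 1, by = 0.1),
                            p_grid = seq(0, 1, length.out = 101L),
                            ctrl = hr_control()) {
  stopifnot(inherits(game, "hr_fitness"))
  if (game$n != 2L) stop("scan_constant_r needs a 2-player game")
  if (any(r_grid < 0 | r_grid > 1) || any(p_grid < 0 | p_grid > 1))
    stop("r_grid and p_grid must lie in [0, 1]")
  out <- lapply(r_grid, function(r) {
    st <- make_structure("constant_r_2player", 2L, list(r = r))
    rows <- lapply(p_grid, function(p) {
      sel <- mean_fitnesses(st, game, p, ctrl)
      cbr <- population_cb(st, game, p, ctrl)
      data.frame(p = p, S = sel$S, hr = cbr$hr, r = cbr$r, c = cbr$c,
                 b = cbr$b)
    })
    do.call(rbind, rows)
  })
  tab <- do.call(rbind, out)
  tab$agree <- sign_tol(tab$S, ctrl$violation_tol) ==
    sign_tol(tab$hr, ctrl$violation_tol)
  tab
}

#' Write a scan or violation-map table as TSV
#'
#' @param tab A data.frame (e.g. from [scan_constant_r()] or the `table`
#'   element of [violation_map()]).
#' @param path Output path.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
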