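#' Population structures: families of group-composition distributions
#'
#' A population structure describes, for every overall cooperator frequency
#' p, how the population is partitioned into groups of size n: `f(p)` returns
#' the vector \eqn{(f_0(p), ..., f_n(p))} of frequencies of groups containing
#' i cooperators.  Consistency requires \eqn{\sum_i f_i(p) = 1} and
#' \eqn{\sum_i (i/n) f_i(p) = p} for all p.
#'
#' Built-in families:
#'
#' * `"constant_r_2player"` (n = 2): \eqn{f_0 = (1-r)(1-p)^2 + r(1-p)},
#'   \eqn{f_1 = (1-r) 2 p (1-p)}, \eqn{f_2 = (1-r) p^2 + r p}.  Relatedness
#'   is the constant r at every p.
#' * `"clonal_or_binomial"` (any n): with probability r the group is clonal
#'   (all-cooperator with probability p, all-defector otherwise), with
#'   probability 1 - r its composition is Binomial(n, p).  For n = 2 this
#'   coincides with `"constant_r_2player"`; relatedness is again constant r.
#' * `"mixture"`: a convex combination of valid structures.  The consistency
#'   constraints are linear in f, so mixtures are automatically valid, and
#'   endpoint profiles combine with the same weights.
#' * `"endpoint_profiles"`: a structure constructed to reproduce
#'   user-supplied rare-mutant profiles u (at p = 0) and ubar (at p = 1).
#'   Only the endpoint behaviour is pinned down; the interior interpolation
#'   path is an explicit, arbitrary choice recorded in the structure's
#'   metadata.
#' * `"custom"`: any user function `f(p)`; endpoint profiles are then
#'   obtained by numerical limits.
#'
#' @param family Family tag (see above).
#' @param n Group size.
#' @param params Named list of family parameters: `r` for the constant-
#'   relatedness families; `components` (list of structures or specs) and
#'   `weights` for mixtures; `u` and `ubar` (weight vectors or
#'   [structure_profile()] objects) for `endpoint_profiles`; `f` (a function
#'   of p) for `custom`.
#'
#' @return An object of class `"hr_structure"`: list with elements `n`,
#'   `family`, `params`, `f` (the composition function), `endpoints` (a
#'   function returning the analytic `list(u, ubar)`, or `NULL` when only the
#'   numerical path is available) and `meta`.
#' @examples
#' st <- make_structure("constant_r_2player", n = 2, params = list(r = 0.3))
#' st$f(0.5)
#' profiles_from_structure(st)$u
#' @export
make_structure <- function(family, n, params = list()) {
  family <- match.arg(family, c("constant_r_2player", "clonal_or_binomial",
                                "mixture", "endpoint_profiles", "custom"))
  n <- as.integer(n)
  if (n < 2L) stop("group size n must be at least 2")
  switch(family,
         constant_r_2player = structure_constant_r2(n, params),
         clonal_or_binomial = structure_clonal_binomial(n, params),
         mixture = structure_mixture(n, params),
         endpoint_profiles = structure_endpoint_profiles(n, params),
         custom = structure_custom(n, params))
}

new_hr_structure <- function(n, family, params, f, endpoints = NULL,
                             meta = list()) {
  structure(list(n = as.integer(n), family = family, params = params,
                 f = f, endpoints = endpoints, meta = meta),
            class = "hr_structure")
}

#' @export
print.hr_structure <- function(x, ...) {
  cat("Population structure: family =", x$family, ", n =", x$n, "\n")
  shown <- x$params[vapply(x$params, is.numeric, TRUE)]
  if (length(shown))
    cat("  params:", paste(names(shown), vapply(shown, function(v)
      paste(format(v), collapse = ","), ""), sep = "=", collapse = "  "), "\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

check_r_param <- function(params) {
  r <- params$r
  if (is.null(r) || !is.numeric(r) || length(r) != 1L || r < 0 || r > 1)
    stop("this family needs a single relatedness parameter r in [0, 1]")
  r
}

structure_constant_r2 <- function(n, params) {
  if (n != 2L) stop("constant_r_2player requires n = 2")
  r <- check_r_param(params)
  f <- function(p) {
    c((1 - r) * (1 - p)^2 + r * (1 - p),
      (1 - r) * 2 * p * (1 - p),
      (1 - r) * p^2 + r * p)
  }
  endpoints <- function() list(
    u = structure_profile(c(0, 1 - r, r), end = "zero"),
    ubar = structure_profile(c(r, 1 - r, 0), end = "one"))
  new_hr_structure(2L, "constant_r_2player", list(r = r), f, endpoints)
}

structure_clonal_binomial <- function(n, params) {
  r <- check_r_param(params)
  f <- function(p) {
    clonal <- numeric(n + 1L)
    clonal[1L] <- 1 - p
    clonal[n + 1L] <- p
    r * clonal + (1 - r) * stats::dbinom(0:n, n, p)
  }
  endpoints <- function() {
    # limit of (i/n) f_i / p: binomial mass at i >= 2 is O(p^i) and vanishes
    u <- numeric(n + 1L)
    u[2L] <- 1 - r
    u[n + 1L] <- r
    ubar <- numeric(n + 1L)
    ubar[1L] <- r
    ubar[n] <- 1 - r
    list(u = structure_profile(u, end = "zero"),
         ubar = structure_profile(ubar, end = "one"))
  }
  new_hr_structure(n, "clonal_or_binomial", list(r = r), f, endpoints)
}

structure_mixture <- function(n, params) {
  comps <- params$components
  w <- as.numeric(params$weights)
  if (is.null(comps) || length(comps) < 1L)
    stop("mixture needs a non-empty list of component structures")
  comps <- lapply(comps, function(cmp) {
    if (inherits(cmp, "hr_structure")) cmp
    else make_structure(cmp$family, cmp$n %||% n, cmp$params %||% list())
  })
  if (length(w) != length(comps))
    stop("mixture weights must match the number of components")
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must be a probability simplex")
  if (any(vapply(comps, function(s) s$n, 1L) != n))
    stop("all mixture components must share group size n = ", n)
  f <- function(p) {
    out <- numeric(n + 1L)
    for (j in seq_along(comps)) out <- out + w[j] * comps[[j]]$f(p)
    out
  }
  endpoints <- NULL
  if (all(vapply(comps, function(s) !is.null(s$endpoints), TRUE))) {
    endpoints <- function() {
      eps <- lapply(comps, function(s) s$endpoints())
      u <- Reduce(`+`, Map(function(e, wt) wt * e$u$weights, eps, w))
      ub <- Reduce(`+`, Map(function(e, wt) wt * e$ubar$weights, eps, w))
      list(u = structure_profile(u, end = "zero"),
           ubar = structure_profile(ub, end = "one"))
    }
  }
  new_hr_structure(n, "mixture", list(weights = w, components = comps),
                   f, endpoints)
}

# Structure realizing prescribed endpoint profiles.  Near p = 0 the groups a
# cooperator can be in are seeded directly from u (f_i = p (n/i) u_i, which
# has exactly the limit u); the leftover frequency sits in all-defector
# groups.  That recipe stays a distribution only while f_0 >= 0, so it is
# faded into the clonal structure away from the boundary.  The same is done
# from the p = 1 side with ubar, and the two halves are glued with weights
# (1 - p, p), which preserves both constraints and both endpoint limits.
structure_endpoint_profiles <- function(n, params) {
  as_weights <- function(x, end) {
    if (inherits(x, "hr_profile")) {
      if (x$end != end) stop("profile supplied for the wrong endpoint")
      if (x$n != n) stop("profile dimension must match n")
      unname(x$weights)
    } else {
      unname(structure_profile(as.numeric(x), end = end)$weights)
    }
  }
  u <- as_weights(params$u %||% stop("endpoint_profiles needs params$u"),
                  "zero")
  ubar <- as_weights(params$ubar %||%
                       stop("endpoint_profiles needs params$ubar"), "one")
  idx <- 0:n
  M0 <- sum(ifelse(idx >= 1, n / pmax(idx, 1) * u, 0))
  M1 <- sum(ifelse(idx <= n - 1, n / pmax(n - idx, 1) * ubar, 0))
  p0 <- 1 / (2 * M0)
  q0 <- 1 / (2 * M1)
  clonal <- function(p) {
    cl <- numeric(n + 1L)
    cl[1L] <- 1 - p
    cl[n + 1L] <- p
    cl
  }
  fA <- function(p) {  # matches u as p -> 0
    seed <- c(1 - p * M0, p * n / idx[-1L] * u[-1L])
    a <- max(0, 1 - p / p0)
    a * seed + (1 - a) * clonal(p)
  }
  fB <- function(p) {  # matches ubar as p -> 1
    seed <- c((1 - p) * n / (n - idx[-(n + 1L)]) * ubar[-(n + 1L)],
              1 - (1 - p) * M1)
    a <- max(0, 1 - (1 - p) / q0)
    a * seed + (1 - a) * clonal(p)
  }
  f <- function(p) (1 - p) * fA(p) + p * fB(p)
  endpoints <- function() list(
    u = structure_profile(u, end = "zero"),
    ubar = structure_profile(ubar, end = "one"))
  new_hr_structure(n, "endpoint_profiles", list(u = u, ubar = ubar), f,
                   endpoints,
                   meta = list(interior_path = paste(
                     "interpolated; only the p = 0 and p = 1 limits are",
                     "constrained by the supplied profiles")))
}

structure_custom <- function(n, params) {
  fn <- params$f
  if (!is.function(fn)) stop("custom structure needs params$f, a function of p")
  f <- function(p) {
    out <- as.numeric(fn(p))
    if (length(out) != n + 1L)
      stop("custom f(p) must return a vector of length n + 1 = ", n + 1L)
    out
  }
  new_hr_structure(n, "custom", params, f, endpoints = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a population structure on a frequency grid
#'
#' Checks the consistency constraints \eqn{\sum_i f_i(p) = 1},
#' \eqn{\sum_i (i/n) f_i(p) = p} and \eqn{f_i(p) \ge 0} on an evenly spaced
#' grid of p values, and reports the maximum violation of each.
#'
#' @param structure An `"hr_structure"`.
#' @param grid_size Number of grid points (at least 3).
#' @param ctrl An [hr_control()] object supplying the tolerance.
#' @return A list of class `"hr_validation"` with elements `passed`,
#'   `max_sum_dev`, `max_mean_dev`, `max_negativity`, `grid_size`, `tol`.
#' @export
validate_structure <- function(structure, grid_size = 101L,
                               ctrl = hr_control()) {
  stopifnot(inherits(structure, "hr_structure"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 3L) stop("grid_size must be at least 3")
  ps <- seq(0, 1, length.out = grid_size)
  i_over_n <- (0:structure$n) / structure$n
  sum_dev <- mean_dev <- neg <- numeric(grid_size)
  for (k in seq_along(ps)) {
    fv <- structure$f(ps[k])
    if (!all(is.finite(fv)))
      stop("invalid structure: non-finite f(p) at p = ", format(ps[k]))
    sum_dev[k] <- abs(sum(fv) - 1)
    mean_dev[k] <- abs(sum(i_over_n * fv) - ps[k])
    neg[k] <- max(0, -min(fv))
  }
  out <- list(passed = max(sum_dev) <= ctrl$structure_tol &&
                max(mean_dev) <= ctrl$structure_tol &&
                max(neg) <= ctrl$structure_tol,
              max_sum_dev = max(sum_dev),
              max_mean_dev = max(mean_dev),
              max_negativity = max(neg),
              grid_size = grid_size,
              tol = ctrl$structure_tol)
  class(out) <- "hr_validation"
  out
}

#' @export
print.hr_validation <- function(x, ...) {
  cat(sprintf(paste0("Structure validation (%d-point grid, tol %.1e): %s\n",
                     "  max |sum f - 1|    = %.3e\n",
                     "  max |mean - p|     = %.3e\n",
                     "  max negativity     = %.3e\n"),
              x$grid_size, x$tol, if (x$passed) "PASS" else "FAIL",
              x$max_sum_dev, x$max_mean_dev, x$max_negativity))
  invisible(x)
}

#' Endpoint population structure profiles u and ubar
#'
#' Extracts the limiting distribution over group compositions experienced by
#' a rare mutant cooperator at p = 0,
#' \eqn{u_i = \lim_{p \downarrow 0} (i/n) f_i(p) / p}, and by a rare mutant
#' defector at p = 1,
#' \eqn{\bar u_i = \lim_{p \uparrow 1} ((n-i)/n) f_i(p) / (1-p)}.
#' Closed-form profiles are used for the built-in families; custom structures
#' fall back on a numerical one-sided limit with one-step Richardson
#' extrapolation (the ratio is evaluated at a geometrically shrinking
#' sequence of p, and successive extrapolants must agree to within
#' `ctrl$richardson_tol`).
#'
#' @param structure An `"hr_structure"`.
#' @param ctrl An [hr_control()] object.
#' @return `list(u = , ubar = )` of [structure_profile()] objects.
#' @export
profiles_from_structure <- function(structure, ctrl = hr_control()) {
  stopifnot(inherits(structure, "hr_structure"))
  if (!is.null(structure$endpoints)) return(structure$endpoints())
  n <- structure$n
  idx <- 0:n
  gu <- function(p) idx / n * structure$f(p) / p
  gub <- function(p) (n - idx) / n * structure$f(1 - p) / p
  u <- numerical_limit(gu, ctrl)
  ubar <- numerical_limit(gub, ctrl)
  u[1L] <- 0
  ubar[n + 1L] <- 0
  list(u = structure_profile(pmax(u, 0) / sum(pmax(u, 0)), end = "zero",
                             tol = ctrl$profile_tol_numeric),
       ubar = structure_profile(pmax(ubar, 0) / sum(pmax(ubar, 0)),
                                end = "one",
                                tol = ctrl$profile_tol_numeric))
}

# one-sided limit of a vector-valued g(p) as p -> 0+, assuming g is one-sided
# differentiable at 0: Richardson step 2 g(p/2) - g(p) kills the linear term
numerical_limit <- function(g, ctrl, p_start = 1e-3, max_halvings = 30L) {
  p <- p_start
  prev <- 2 * g(p / 2) - g(p)
  for (k in seq_len(max_halvings)) {
    p <- p / 2
    cur <- 2 * g(p / 2) - g(p)
    if (!all(is.finite(cur)))
      stop("numerical endpoint limit failed: non-finite values near p = ",
           format(p))
    if (max(abs(cur - prev)) < ctrl$richardson_tol) return(cur)
    prev <- cur
  }
  stop("numerical endpoint limit did not converge after ", max_halvings,
       " halvings (last change ", format(max(abs(cur - prev))),
       "); custom structures must be one-sided differentiable at the ",
       "endpoints")
}

#' Conditional group-composition distributions at an interior frequency
#'
#' At 0 < p < 1, the distribution of compositions seen by a randomly chosen
#' cooperator is \eqn{v^C_i = (i/n) f_i(p) / p}, and by a randomly chosen
#' defector \eqn{v^D_i = ((n-i)/n) f_i(p) / (1-p)}.  These are the interior
#' analogues of the endpoint profiles u and ubar.
#'
#' @param structure An `"hr_structure"`.
#' @param p Frequency strictly inside (0, 1).
#' @param ctrl An [hr_control()] object.
#' @return `list(vC = , vD = )` of interior [structure_profile()] objects.
#' @export
conditional_distributions <- function(structure, p, ctrl = hr_control()) {
  stopifnot(inherits(structure, "hr_structure"))
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1); use profiles_from_structure() ",
         "for the endpoint limits")
  n <- structure$n
  idx <- 0:n
  fv <- structure$f(p)
  vC <- idx / n * fv / p
  vD <- (n - idx) / n * fv / (1 - p)
  list(vC = structure_profile(vC, end = "interior", p = p,
                              tol = ctrl$profile_tol_numeric),
       vD = structure_profile(vD, end = "interior", p = p,
                              tol = ctrl$profile_tol_numeric))
}

# evaluate code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Random valid population structure
#'
#' Draws a reproducible convex mixture of constant-relatedness
#' (clonal-or-binomial) components with random r values and random simplex
#' weights.  By construction the result always satisfies the consistency
#' constraints, which makes it a convenient fixture for property tests.
#'
#' @param seed Integer seed; the same seed always yields the same structure.
#' @param n Group size.
#' @param k_components Number of mixture components (>= 1).
#' @return An `"hr_structure"` of family `"mixture"` (or a single
#'   clonal-or-binomial structure when `k_components = 1`).
#' @export
generate_random_structure <- function(seed, n = 2L, k_components = 3L) {
  stopifnot(k_components >= 1L)
  with_seed(seed, {
    rs <- stats::runif(k_components)
    w <- stats::runif(k_components)
    w <- w / sum(w)
    if (k_components == 1L)
      return(make_structure("clonal_or_binomial", n, list(r = rs)))
    comps <- lapply(rs, function(r)
      make_structure("clonal_or_binomial", n, list(r = r)))
    make_structure("mixture", n, list(components = comps, weights = w))
  })
}

#' Read a population structure from a JSON specification
#'
#' Format: `{"family": "...", "n": ..., "params": {...}}`.  Mixtures nest
#' component specifications under `params$components` with `params$weights`;
#' `endpoint_profiles` takes `params$u` and `params$ubar` as weight arrays.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return An `"hr_structure"`.
#' @export
read_structure_json <- function(path) {
  spec <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  spec_to_structure(spec)
}

spec_to_structure <- function(spec) {
  if (is.null(spec$family) || is.null(spec$n))
    stop("structure spec needs fields 'family' and 'n'")
  params <- spec$params %||% list()
  if (identical(spec$family, "mixture")) {
    params$components <- lapply(params$components, spec_to_structure)
  }
  make_structure(spec$family, spec$n, params)
}
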