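#' Population structure profile
#'
#' The distribution over group compositions experienced by a focal
#' individual.  At the invasion boundaries these are the limiting profiles:
#' `end = "zero"` is the profile \eqn{u} of a rare mutant cooperator
#' (\eqn{u_i = \lim_{p \downarrow 0} (i/n) f_i(p) / p}), which has no mass at
#' i = 0 because the focal itself cooperates; `end = "one"` is the profile
#' \eqn{\bar u} of a rare mutant defector, with no mass at i = n.  Interior
#' profiles (`end = "interior"`) are the conditional composition
#' distributions of a cooperator or defector at frequency p.
#'
#' @param weights Numeric vector of length n + 1, indexed by composition
#'   i = 0..n; non-negative and summing to 1 (within `tol`).
#' @param end One of `"zero"`, `"one"`, `"interior"`.
#' @param p The frequency the profile refers to (0, 1, or interior value).
#' @param tol Normalisation tolerance.
#' @return An object of class `"hr_profile"`.
#' @export
structure_profile <- function(weights, end = c("zero", "one", "interior"),
                              p = switch(end, zero = 0, one = 1, NA_real_),
                              tol = 1e-9) {
  end <- match.arg(end)
  weights <- as.numeric(weights)
  n <- length(weights) - 1L
  if (n < 1L) stop("profile needs weights over compositions 0..n with n >= 1")
  if (any(weights < -tol))
    stop("profile weights must be non-negative")
  weights <- pmax(weights, 0)
  s <- sum(weights)
  if (abs(s - 1) > tol)
    stop("profile weights must sum to 1 (got ", format(s), ")")
  weights <- weights / s
  if (end == "zero" && weights[1L] > tol)
    stop("a focal cooperator's group contains at least one cooperator: ",
         "u must have no mass at i = 0")
  if (end == "one" && weights[n + 1L] > tol)
    stop("a focal defector's group contains at most n - 1 cooperators: ",
         "ubar must have no mass at i = n")
  if (end == "zero") weights[1L] <- 0
  if (end == "one") weights[n + 1L] <- 0
  names(weights) <- as.character(0:n)
  structure(list(n = n, end = end, p = p, weights = weights),
            class = "hr_profile")
}

#' @export
print.hr_profile <- function(x, ...) {
  lab <- switch(x$end, zero = "u (rare cooperator, p = 0)",
                one = "ubar (rare defector, p = 1)",
                interior = sprintf("conditional profile at p = %g", x$p))
  cat("Population structure profile:", lab, "\n")
  w <- x$weights[x$weights > 0]
  print(round(w, 6))
  invisible(x)
}

# sparse constructor: mass `w` on compositions `on`, zeros elsewhere
profile_on <- function(n, on, w, end, p = switch(end, zero = 0, one = 1,
                                                 NA_real_)) {
  weights <- numeric(n + 1L)
  weights[on + 1L] <- w
  structure_profile(weights, end = end, p = p)
}

#' Mirror a profile between the two invasion boundaries
#'
#' Maps the rare-cooperator profile u into the rare-defector profile with
#' \eqn{\bar u_i = u_{n - i}}, i.e. the population structure treats the two
#' types symmetrically.
#'
#' @param profile An `"hr_profile"` with `end = "zero"` or `"one"`.
#' @return The mirrored `"hr_profile"` at the opposite end.
#' @export
mirror_profile <- function(profile) {
  stopifnot(inherits(profile, "hr_profile"))
  if (profile$end == "interior")
    stop("only endpoint profiles can be mirrored")
  structure_profile(rev(profile$weights),
                    end = if (profile$end == "zero") "one" else "zero")
}

#' Expected composition moments of a profile
#'
#' @param profile An `"hr_profile"`.
#' @param power Moment order (1 for E[i], 2 for E[i^2], ...).
#' @return The moment \eqn{E[i^{power}]} under the profile's weights.
#' @export
profile_moment <- function(profile, power = 1) {
  stopifnot(inherits(profile, "hr_profile"))
  sum(profile$weights * (0:profile$n)^power)
}

#' Write a profile as JSON
#'
#' Serialises to `{"end": ..., "p": ..., "weights": [...]}`.
#'
#' @param profile An `"hr_profile"`.
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @export
write_profile_json <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "hr_profile"))
  obj <- list(end = profile$end, p = profile$p,
              weights = unname(profile$weights))
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
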