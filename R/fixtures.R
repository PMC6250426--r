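#' Bundled worked-example systems
#'
#' Four n = 10 fitness functions, each paired with a minimal-support
#' endpoint profile (and its mirror image at p = 1), chosen to exhibit the
#' main qualitative regimes of the counterfactual Hamilton's rule:
#'
#' * `linear_low_assortment`: equal-gains (linear) payoffs
#'   \eqn{\pi_C(i) = 0.6 + 2i/10}, \eqn{\pi_D(i) = 1 + 2i/10}, under weak
#'   assortment (u puts mass 0.64/0.36 on compositions 1/2).  Cooperation is
#'   selected against at both ends (S = -0.128) and Hamilton's rule agrees
#'   exactly.
#' * `linear_high_assortment`: the same payoffs under stronger assortment
#'   (mass 0.2/0.8 on compositions 2/3); cooperation is selected for
#'   (S = +0.16) and again rb - c = S.
#' * `quadratic_synergy`: \eqn{\pi_C(i) = 0.5 + 2(i/10)^2},
#'   \eqn{\pi_D(i) = 1 + 2(i/10)^2} with mass 0.45/0.30/0.25 on 2/3/4.
#'   Synergistic: selected against at p = 0 (S = -0.33), selected for at
#'   p = 1 (S = +0.45); Hamilton's rule can disagree with selection but not
#'   at a stable state.
#' * `root_antisynergy`: \eqn{\pi_C(i) = 0.5 + 2\sqrt{i/10}},
#'   \eqn{\pi_D(i) = 1 + 2\sqrt{i/10}}.  Anti-synergistic (diminishing
#'   returns): supports mixed equilibria at which rb - c is nonzero.  No
#'   endpoint profile is bundled for this system; pair it with any structure
#'   (its interesting behaviour is interior).
#'
#' The first three profiles are synthetic minimal-support distributions:
#' the linear systems depend on the profile only through the mean
#' composition E\[i\], and the quadratic one only through E\[i^2\], so these
#' few-atom profiles are the simplest representatives of their equivalence
#' classes.  Every bundled ubar is the mirror image
#' \eqn{\bar u_i = u_{n - i}}.
#'
#' @return A named list; each element is a list with components `fitness`
#'   (an [fitness_function()]), `u`, `ubar` ([structure_profile()] objects,
#'   or `NULL` for `root_antisynergy`).
#' @examples
#' sys <- demo_systems()$linear_low_assortment
#' mean_fitnesses(sys$u, sys$fitness, p = 0)
#' @export
demo_systems <- function() {
  n <- 10L
  lin <- fitness_function(piC = 0.6 + 2 * (1:n) / n,
                          piD = 1 + 2 * (0:(n - 1)) / n)
  quad <- fitness_function(piC = 0.5 + 2 * ((1:n) / n)^2,
                           piD = 1 + 2 * ((0:(n - 1)) / n)^2)
  rt <- fitness_function(piC = 0.5 + 2 * sqrt((1:n) / n),
                         piD = 1 + 2 * sqrt((0:(n - 1)) / n))
  u_low <- profile_on(n, on = c(1, 2), w = c(0.64, 0.36), end = "zero")
  u_high <- profile_on(n, on = c(2, 3), w = c(0.2, 0.8), end = "zero")
  u_quad <- profile_on(n, on = c(2, 3, 4), w = c(0.45, 0.30, 0.25),
                       end = "zero")
  list(
    linear_low_assortment = list(fitness = lin, u = u_low,
                                 ubar = mirror_profile(u_low)),
    linear_high_assortment = list(fitness = lin, u = u_high,
                                  ubar = mirror_profile(u_high)),
    quadratic_synergy = list(fitness = quad, u = u_quad,
                             ubar = mirror_profile(u_quad)),
    root_antisynergy = list(fitness = rt, u = NULL, ubar = NULL))
}

#' Bundled 2-player demonstration games
#'
#' Two prisoner's dilemmas that bracket the synergy spectrum:
#'
#' * `synergy`: \eqn{\pi_C(1) = 0.1, \pi_C(2) = 3, \pi_D(0) = 2,
#'   \pi_D(1) = 3.1}.  Cooperating pays off strongly only with a fellow
#'   cooperator.  Under any constant-relatedness structure, selection always
#'   carries the population out of the region where Hamilton's rule
#'   disagrees with selection, so no violation is observable at a stable
#'   state.
#' * `antisynergy`: \eqn{\pi_C(1) = 1.9, \pi_C(2) = 3, \pi_D(0) = 2,
#'   \pi_D(1) = 4.9}.  Defecting against a cooperator pays best; mixed
#'   stable equilibria exist at which rb - c is nonzero — an in-equilibrium
#'   violation.
#'
#' @return A named list of two `"hr_fitness"` objects with n = 2.
#' @examples
#' g <- demo_games()$antisynergy
#' st <- make_structure("constant_r_2player", 2, list(r = 0.3))
#' find_equilibria(st, g)
#' @export
demo_games <- function() {
  list(synergy = game_matrix(piC1 = 0.1, piC2 = 3, piD0 = 2, piD1 = 3.1),
       antisynergy = game_matrix(piC1 = 1.9, piC2 = 3, piD0 = 2,
                                 piD1 = 4.9))
}

#' Write the bundled fixtures to disk
#'
#' Dumps every [demo_systems()] fitness function as CSV and every bundled
#' endpoint profile as JSON into `dir`.
#'
#' @param dir Output directory (created if missing).
#' @return The paths written, invisibly.
#' @export
write_fixtures <- function(dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  sys <- demo_systems()
  for (nm in names(sys)) {
    fp <- file.path(dir, paste0(nm, "_fitness.csv"))
    write_fitness_csv(sys[[nm]]$fitness, fp)
    paths <- c(paths, fp)
    if (!is.null(sys[[nm]]$u)) {
      up <- file.path(dir, paste0(nm, "_u.json"))
      ubp <- file.path(dir, paste0(nm, "_ubar.json"))
      write_profile_json(sys[[nm]]$u, up)
      write_profile_json(sys[[nm]]$ubar, ubp)
      paths <- c(paths, up, ubp)
    }
  }
  gm <- demo_games()
  for (nm in names(gm)) {
    fp <- file.path(dir, paste0("game_", nm, ".csv"))
    write_fitness_csv(gm[[nm]], fp)
    paths <- c(paths, fp)
  }
  invisible(paths)
}
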