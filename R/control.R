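#' Numerical tolerances and grid defaults
#'
#' All tolerances used by the validation, profile-extraction, equilibrium and
#' regression code live in one control object so that every consumer agrees
#' on what "zero" means.
#'
#' @param structure_tol Maximum violation of \eqn{\sum_i f_i = 1},
#'   \eqn{\sum_i (i/n) f_i = p} and \eqn{f_i \ge 0} allowed for a structure
#'   to validate (analytic families satisfy these to machine precision).
#' @param profile_tol_analytic Normalisation tolerance for profiles obtained
#'   from closed-form endpoint formulas.
#' @param profile_tol_numeric Normalisation tolerance for profiles obtained
#'   by numerical limits.
#' @param richardson_tol Convergence threshold for the Richardson-extrapolated
#'   endpoint limits: successive extrapolants must differ by less than this.
#' @param root_tol Tolerance on \eqn{|S(p)|} when refining interior roots of
#'   the selection differential.
#' @param equal_gains_tol Tolerance used when deciding that the two synergy
#'   inequalities hold with equality (equal gains from switching).
#' @param identity_tol Tolerance on the Price/OLS identity residual.
#' @param violation_tol \eqn{|rb - c|} above this at a stable state counts as
#'   an in-equilibrium violation.
#' @param grid_size Default number of points in frequency grids.
#'
#' @return A named list of class `"hr_control"`.
#' @export
hr_control <- function(structure_tol = 1e-9,
                       profile_tol_analytic = 1e-12,
                       profile_tol_numeric = 1e-6,
                       richardson_tol = 1e-7,
                       root_tol = 1e-10,
                       equal_gains_tol = 1e-9,
                       identity_tol = 1e-10,
                       violation_tol = 1e-8,
                       grid_size = 1001L) {
  ctrl <- list(structure_tol = structure_tol,
               profile_tol_analytic = profile_tol_analytic,
               profile_tol_numeric = profile_tol_numeric,
               richardson_tol = richardson_tol,
               root_tol = root_tol,
               equal_gains_tol = equal_gains_tol,
               identity_tol = identity_tol,
               violation_tol = violation_tol,
               grid_size = as.integer(grid_size))
  stopifnot(all(vapply(ctrl[1:8], function(x) is.numeric(x) && x > 0, TRUE)))
  class(ctrl) <- "hr_control"
  ctrl
}

# signum with a dead zone: values within tol of zero count as zero
sign_tol <- function(x, tol) {
  s <- sign(x)
  s[abs(x) <= tol] <- 0
  s
}
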