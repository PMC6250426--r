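#' Fitness function for cooperators and defectors in groups of size n
#'
#' A fitness function assigns a payoff to every individual as a function of
#' its own type and the number of cooperators in its group (itself included).
#' `piC[i]` is the fitness of a cooperator in a group containing `i`
#' cooperators, defined for `i = 1, ..., n`; `piD[i]` is the fitness of a
#' defector in a group containing `i` cooperators, defined for
#' `i = 0, ..., n - 1`.  The impossible entries — a cooperator in a group
#' with zero cooperators, a defector in a group of n cooperators — do not
#' exist and are never stored.
#'
#' @param piC Numeric vector of length n: cooperator fitness at
#'   `i = 1, ..., n` cooperators.
#' @param piD Numeric vector of length n: defector fitness at
#'   `i = 0, ..., n - 1` cooperators.
#'
#' @return An object of class `"hr_fitness"`: a list with elements `n`,
#'   `piC` (named by composition 1..n) and `piD` (named by composition
#'   0..n-1).
#' @seealso [game_matrix()] for the 2-player convenience constructor,
#'   [pi_C()] and [pi_D()] for bounds-checked access.
#' @examples
#' # linear public-goods payoffs for groups of 10
#' ff <- fitness_function(piC = 0.6 + 2 * (1:10) / 10,
#'                        piD = 1 + 2 * (0:9) / 10)
#' pi_C(ff, 3)
#' @export
fitness_function <- function(piC, piD) {
  piC <- as.numeric(piC)
  piD <- as.numeric(piD)
  n <- length(piC)
  if (n < 2L)
    stop("group size n must be at least 2 (got piC of length ", n, ")")
  if (length(piD) != n)
    stop("piC (i = 1..n) and piD (i = 0..n-1) must both have length n; got ",
         n, " and ", length(piD))
  if (!all(is.finite(piC)) || !all(is.finite(piD)))
    stop("all fitness values must be finite")
  names(piC) <- as.character(seq_len(n))
  names(piD) <- as.character(0:(n - 1L))
  structure(list(n = as.integer(n), piC = piC, piD = piD),
            class = "hr_fitness")
}

#' @export
print.hr_fitness <- function(x, ...) {
  cat("Fitness function, group size n =", x$n, "\n")
  tab <- data.frame(i = 0:x$n,
                    pi_C = c(NA, unname(x$piC)),
                    pi_D = c(unname(x$piD), NA))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Bounds-checked fitness accessors
#'
#' `pi_C(ff, i)` returns the fitness of a cooperator in a group with `i`
#' cooperators (valid for `i` in 1..n); `pi_D(ff, i)` the fitness of a
#' defector (valid for `i` in 0..n-1).  Out-of-domain compositions are an
#' error, never silently 0 or NA.
#'
#' @param ff An [fitness_function()] object.
#' @param i Integer vector of group compositions (number of cooperators).
#' @return Numeric vector of fitness values.
#' @export
pi_C <- function(ff, i) {
  stopifnot(inherits(ff, "hr_fitness"))
  if (any(i < 1L | i > ff$n))
    stop("pi_C(i) is defined only for i in 1..n; got i = ",
         paste(i[i < 1L | i > ff$n], collapse = ", "))
  unname(ff$piC[i])
}

#' @rdname pi_C
#' @export
pi_D <- function(ff, i) {
  stopifnot(inherits(ff, "hr_fitness"))
  if (any(i < 0L | i > ff$n - 1L))
    stop("pi_D(i) is defined only for i in 0..n-1; got i = ",
         paste(i[i < 0L | i > ff$n - 1L], collapse = ", "))
  unname(ff$piD[i + 1L])
}

#' 2-player game matrix
#'
#' Convenience constructor for dyadic (n = 2) games, taking the four payoffs
#' of the cooperate/defect stage game.  Converts losslessly to an
#' [fitness_function()] with n = 2.
#'
#' @param piC1 Cooperator's payoff against a defector (\eqn{\pi_C(1)}).
#' @param piC2 Cooperator's payoff against a cooperator (\eqn{\pi_C(2)}).
#' @param piD0 Defector's payoff against a defector (\eqn{\pi_D(0)}).
#' @param piD1 Defector's payoff against a cooperator (\eqn{\pi_D(1)}).
#' @return An `"hr_fitness"` object with n = 2.
#' @examples
#' game_matrix(piC1 = 1.9, piC2 = 3, piD0 = 2, piD1 = 4.9)
#' @export
game_matrix <- function(piC1, piC2, piD0, piD1) {
  fitness_function(piC = c(piC1, piC2), piD = c(piD0, piD1))
}

#' Linear (equal-gains) fitness function
#'
#' Builds the fitness function \eqn{\pi_C(i) = baseC + slope \cdot i},
#' \eqn{\pi_D(i) = baseD + slope \cdot i}.  With a common slope every switch
#' from defection to cooperation has the same effect on each group mate
#' regardless of composition ("equal gains from switching"), which makes the
#' counterfactual Hamilton's rule coincide exactly with the direction of
#' selection for every population structure.
#'
#' @param n Group size.
#' @param baseC,baseD Intercepts of the cooperator and defector payoff lines.
#' @param slope Common per-cooperator payoff increment.
#' @return An `"hr_fitness"` object.
#' @export
linear_fitness <- function(n, baseC, baseD, slope) {
  fitness_function(piC = baseC + slope * seq_len(n),
                   piD = baseD + slope * (0:(n - 1L)))
}

#' Read / write a fitness function as CSV
#'
#' The on-disk format has a header `i,pi_C,pi_D` and one row per composition
#' `i = 0..n`; `pi_C` is empty at `i = 0` and `pi_D` empty at `i = n`,
#' mirroring the fact that those entries do not exist.
#'
#' @param path File path.
#' @return `read_fitness_csv()` returns an `"hr_fitness"` object;
#'   `write_fitness_csv()` returns `path` invisibly.
#' @export
read_fitness_csv <- function(path) {
  tab <- utils::read.csv(path, header = TRUE)
  need <- c("i", "pi_C", "pi_D")
  if (!all(need %in% names(tab)))
    stop("fitness CSV must have columns ", paste(need, collapse = ", "))
  tab <- tab[order(tab$i), ]
  n <- max(tab$i)
  if (!identical(as.integer(tab$i), 0:n))
    stop("fitness CSV must have one row per composition i = 0..n")
  fitness_function(piC = tab$pi_C[tab$i >= 1], piD = tab$pi_D[tab$i <= n - 1])
}

#' @rdname read_fitness_csv
#' @param ff An `"hr_fitness"` object.
#' @export
write_fitness_csv <- function(ff, path) {
  stopifnot(inherits(ff, "hr_fitness"))
  tab <- data.frame(i = 0:ff$n,
                    pi_C = c(NA, unname(ff$piC)),
                    pi_D = c(unname(ff$piD), NA))
  utils::write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
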