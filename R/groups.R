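#' Estimate a fitness function from group-composition data
#'
#' Empirical tests of the counterfactual Hamilton's rule need the fitness
#' function itself, estimated without imposing linearity.  This takes
#' focal-individual records labelled by group composition — `(i, type, w)`
#' with `i` the number of cooperators in the focal's group (itself
#' included) — and estimates \eqn{\hat\pi_C(i)} and \eqn{\hat\pi_D(i)} as
#' cell means of the saturated model.  It then tests "generalized equal
#' gains from switching" by comparing the saturated cell-mean model with
#' the constrained model in which both payoff schedules are linear in `i`
#' with a common slope (the exact shape under which Hamilton's rule can
#' never disagree with selection).  Rejection of that constrained model is
#' the statistical licence for looking for violations.
#'
#' @param group_records Data frame with columns `group_id`, `i`, `type`
#'   (`"C"` or `"D"`), `w`.
#' @param n Group size; inferred as `max(i[type == "C"], i[type == "D"] + 1)`
#'   when `NULL`.
#' @param alpha Significance level for the equal-gains test.
#' @return A list of class `"hr_pi_estimate"`: `n`, `piC_hat`, `piD_hat`,
#'   `fitness` (an [fitness_function()] when every cell is observed, else
#'   `NULL`), `cells` (per-cell counts and means), `missing` (character
#'   vector of unobserved cells), `equal_gains_test` (`F`, `df1`, `df2`,
#'   `p_value`, `verdict`, or `NULL` when not estimable).
#' @export
estimate_pi_from_groups <- function(group_records, n = NULL, alpha = 0.05) {
  gr <- group_records
  need <- c("i", "type", "w")
  if (!all(need %in% names(gr)))
    stop("group records need columns ", paste(need, collapse = ", "))
  if (!all(gr$type %in% c("C", "D")))
    stop("type must be 'C' or 'D'")
  if (is.null(n))
    n <- max(c(gr$i[gr$type == "C"], gr$i[gr$type == "D"] + 1L))
  n <- as.integer(n)
  if (any(gr$i[gr$type == "C"] < 1L | gr$i[gr$type == "C"] > n) ||
      any(gr$i[gr$type == "D"] < 0L | gr$i[gr$type == "D"] > n - 1L))
    stop("composition i out of range for the stated type and n = ", n)
  cell <- interaction(gr$type, gr$i, drop = FALSE)
  means <- tapply(gr$w, list(gr$type, gr$i), mean)
  counts <- table(gr$type, gr$i)
  cell_mean <- function(type, i) {
    ch <- as.character(i)
    if (type %in% rownames(means) && ch %in% colnames(means) &&
        !is.na(means[type, ch])) means[type, ch] else NA_real_
  }
  piC_hat <- vapply(1:n, function(i) cell_mean("C", i), 0)
  piD_hat <- vapply(0:(n - 1L), function(i) cell_mean("D", i), 0)
  names(piC_hat) <- as.character(1:n)
  names(piD_hat) <- as.character(0:(n - 1L))
  mc <- (1:n)[is.na(piC_hat)]
  md <- (0:(n - 1L))[is.na(piD_hat)]
  missing <- c(if (length(mc)) paste0("pi_C(", mc, ")"),
               if (length(md)) paste0("pi_D(", md, ")"))
  missing <- as.character(missing)
  fitness <- NULL
  if (length(missing) == 0L) {
    fitness <- fitness_function(piC = piC_hat, piD = piD_hat)
  } else {
    warning("partial estimate; unobserved composition cells: ",
            paste(missing, collapse = ", "))
  }
  eg <- NULL
  cell_f <- droplevels(interaction(gr$type, gr$i))
  n_cells <- nlevels(cell_f)
  if (length(missing) == 0L && nrow(gr) > n_cells + 1L) {
    sat <- stats::lm(w ~ 0 + cell_f, data = data.frame(w = gr$w, cell_f))
    lin <- stats::lm(w ~ type + i, data = gr)
    an <- stats::anova(lin, sat)
    eg <- list(F = an$F[2L], df1 = an$Df[2L], df2 = an$Res.Df[2L],
               p_value = an$`Pr(>F)`[2L], alpha = alpha,
               verdict = if (an$`Pr(>F)`[2L] < alpha)
                 "equal gains rejected" else "equal gains not rejected")
  }
  structure(list(n = n, piC_hat = piC_hat, piD_hat = piD_hat,
                 fitness = fitness,
                 cells = data.frame(type = rep(rownames(counts),
                                               ncol(counts)),
                                    i = rep(as.integer(colnames(counts)),
                                            each = nrow(counts)),
                                    count = as.vector(counts)),
                 missing = missing, equal_gains_test = eg),
            class = "hr_pi_estimate")
}

#' @export
print.hr_pi_estimate <- function(x, ...) {
  cat("Estimated fitness function (cell means), n =", x$n, "\n")
  if (length(x$missing))
    cat("  missing cells:", paste(x$missing, collapse = ", "), "\n")
  if (!is.null(x$equal_gains_test))
    cat(sprintf("  equal-gains test: F(%d, %d) = %.4g, p = %.4g -> %s\n",
                x$equal_gains_test$df1, x$equal_gains_test$df2,
                x$equal_gains_test$F, x$equal_gains_test$p_value,
                x$equal_gains_test$verdict))
  invisible(x)
}

#' Simulate focal-individual records by group composition
#'
#' Draws `n_per_cell` focal observations for every feasible (type,
#' composition) cell of a fitness function, with Gaussian measurement noise
#' — the design an experiment estimating the fitness function would use.
#'
#' @param fitness An [fitness_function()].
#' @param n_per_cell Observations per cell.
#' @param sd Noise standard deviation.
#' @param seed Optional integer seed.
#' @return A data.frame with columns `group_id`, `i`, `type`, `w`.
#' @export
simulate_group_records <- function(fitness, n_per_cell = 50L, sd = 0.1,
                                   seed = NULL) {
  stopifnot(inherits(fitness, "hr_fitness"))
  n <- fitness$n
  gen <- function() {
    iC <- rep(1:n, each = n_per_cell)
    iD <- rep(0:(n - 1L), each = n_per_cell)
    wC <- pi_C(fitness, iC) + stats::rnorm(length(iC), sd = sd)
    wD <- pi_D(fitness, iD) + stats::rnorm(length(iD), sd = sd)
    data.frame(group_id = seq_len(length(iC) + length(iD)),
               i = c(iC, iD),
               type = rep(c("C", "D"), c(length(iC), length(iD))),
               w = c(wC, wD))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Rejection rate of the equal-gains test under simulation
#'
#' Repeatedly simulates group records from a fitness function and applies
#' the equal-gains F-test of [estimate_pi_from_groups()].  With a linear
#' (equal-gains) fitness function the rejection rate estimates the type-I
#' error; with a non-linear one it estimates power.
#'
#' @param fitness The generating [fitness_function()].
#' @param reps Number of replicate experiments.
#' @param n_per_cell,sd Passed to [simulate_group_records()].
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @return A list: `rejection_rate`, `reps`, `mc_se`.
#' @export
equal_gains_power <- function(fitness, reps = 500L, n_per_cell = 50L,
                              sd = 0.1, alpha = 0.05, seed = 1L) {
  rej <- with_seed(seed, {
    vapply(seq_len(reps), function(k) {
      gr <- simulate_group_records(fitness, n_per_cell = n_per_cell,
                                   sd = sd)
      est <- estimate_pi_from_groups(gr, n = fitness$n, alpha = alpha)
      est$equal_gains_test$p_value < alpha
    }, TRUE)
  })
  rate <- mean(rej)
  list(rejection_rate = rate, reps = reps,
       mc_se = sqrt(rate * (1 - rate) / reps))
}

#' Read / write group records as TSV
#'
#' Columns: `group_id`, `i`, `type`, `w`.
#'
#' @param path File path.
#' @return `read_group_records_tsv()` returns the records data.frame.
#' @export
read_group_records_tsv <- function(path) {
  gr <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("i", "type", "w") %in% names(gr)))
    stop("group records TSV must have columns i, type, w")
  gr
}

#' @rdname read_group_records_tsv
#' @param group_records Group records data.frame.
#' @export
write_group_records_tsv <- function(group_records, path) {
  utils::write.table(group_records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
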