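#' Regression specification for the OLS version of Hamilton's rule
#'
#' The regression method defines minus the cost of cooperation as the
#' partial regression coefficient of an individual's own cooperativeness in
#' an OLS regression of fitness, and the benefit per relationship class
#' (siblings, cousins, ...) as the coefficient of that class's partner
#' cooperativeness.  Which classes and which higher-order terms enter is the
#' *specification*; costs and benefits generally change with it even though
#' every linear specification yields a Hamilton's rule that matches the
#' direction of selection.
#'
#' Built-in specifications: `"I"` — siblings only; `"II"` — siblings and
#' cousins; `"III"` — II plus the own-by-sibling interaction; `"IV"` — II
#' plus a quadratic sibling term.
#'
#' @param id One of `"I"`, `"II"`, `"III"`, `"IV"`, `"custom"`.
#' @param classes For `"custom"`: character vector of relationship-class
#'   prefixes present in the records (e.g. `c("sib", "cou")`).
#' @param interactions For `"custom"`: list of character pairs, each either
#'   two class names or `"se"` and a class name.
#' @param quadratics For `"custom"`: character vector of class names whose
#'   squared aggregated trait enters.
#' @param aggregate How to aggregate multiple partners of one class:
#'   `"mean"` (default; coefficients read as the benefit of a fully
#'   cooperative class) or `"sum"`.
#' @return A list of class `"hr_spec"`.
#' @export
hr_spec <- function(id = c("I", "II", "III", "IV", "custom"),
                    classes = NULL, interactions = NULL, quadratics = NULL,
                    aggregate = c("mean", "sum")) {
  id <- match.arg(id)
  aggregate <- match.arg(aggregate)
  preset <- switch(id,
    I = list(classes = "sib", interactions = NULL, quadratics = NULL),
    II = list(classes = c("sib", "cou"), interactions = NULL,
              quadratics = NULL),
    III = list(classes = c("sib", "cou"),
               interactions = list(c("se", "sib")), quadratics = NULL),
    IV = list(classes = c("sib", "cou"), interactions = NULL,
              quadratics = "sib"),
    custom = list(classes = classes, interactions = interactions,
                  quadratics = quadratics))
  if (is.null(preset$classes) || length(preset$classes) < 1L)
    stop("a specification needs at least one relationship class")
  structure(list(id = id, classes = preset$classes,
                 interactions = preset$interactions,
                 quadratics = preset$quadratics, aggregate = aggregate),
            class = "hr_spec")
}

spec_terms <- function(spec) {
  terms <- c("x_se", spec$classes)
  for (ia in spec$interactions) {
    cols <- ifelse(ia == "se", "x_se", ia)
    terms <- c(terms, paste(cols, collapse = ":"))
  }
  for (q in spec$quadratics) terms <- c(terms, paste0(q, "_sq"))
  terms
}

is_linear_spec <- function(spec) {
  is.null(spec$interactions) && is.null(spec$quadratics)
}

# Aggregate partner columns (class_1, class_2, ...) into one column per
# relationship class and attach interaction / quadratic columns.
build_design <- function(records, spec) {
  stopifnot(is.data.frame(records))
  if (!all(c("x_se", "w") %in% names(records)))
    stop("records need columns x_se and w")
  if (!all(is.finite(records$x_se)) || !all(is.finite(records$w)))
    stop("all traits and fitness values must be finite")
  out <- data.frame(w = records$w, x_se = records$x_se)
  for (cl in spec$classes) {
    cols <- grep(paste0("^", cl, "(_[0-9]+)?$"), names(records),
                 value = TRUE)
    if (length(cols) == 0L)
      stop("records contain no partner columns for class '", cl, "'")
    vals <- as.matrix(records[cols])
    if (!all(is.finite(vals)))
      stop("all traits and fitness values must be finite")
    out[[cl]] <- if (spec$aggregate == "mean") rowMeans(vals)
    else rowSums(vals)
  }
  for (ia in spec$interactions) {
    cols <- ifelse(ia == "se", "x_se", ia)
    out[[paste(cols, collapse = ":")]] <- out[[cols[1L]]] * out[[cols[2L]]]
  }
  for (q in spec$quadratics) out[[paste0(q, "_sq")]] <- out[[q]]^2
  out
}

#' Ordinary least squares fit of fitness on cooperativeness
#'
#' Fits fitness on own cooperativeness and the aggregated partner
#' cooperativeness of each relationship class in the specification (plus any
#' interaction or quadratic terms), with an intercept.  Residuals are
#' orthogonal to every regressor by construction.
#'
#' @param records Data frame of individual records: columns `x_se` (own
#'   trait), `w` (fitness), and per-class partner columns `sib_1`, ...,
#'   `cou_1`, ... (see [read_records_tsv()]).
#' @param spec An [hr_spec()].
#' @return Named numeric vector of coefficients (including the intercept).
#' @export
ols_fit <- function(records, spec) {
  design <- build_design(records, spec)
  terms <- setdiff(names(design), "w")
  fml <- stats::reformulate(sprintf("`%s`", terms), response = "w")
  fit <- stats::lm(fml, data = design)
  cf <- stats::coef(fit)
  names(cf) <- sub("^`|`$", "", names(cf))
  if (anyNA(cf))
    stop("design matrix is rank deficient; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  cf
}

pop_cov <- function(a, b) mean((a - mean(a)) * (b - mean(b)))

#' Hamilton's rule by the regression method
#'
#' Computes, for the given specification: the cost `c` (minus the
#' coefficient of own cooperativeness), the benefit `b_k` of each
#' relationship class (its coefficient), the relatedness
#' `r_k = cov(x_k, x_se) / var(x_se)`, and the observed one-generation
#' change in mean cooperativeness `delta_xbar` under faithful transmission
#' (offspring count `w`, offspring copying the parental trait), i.e. the
#' Price-equation quantity \eqn{\mathrm{cov}(w, x_{se}) / \bar w}.
#'
#' For every *linear* specification, OLS orthogonality turns the Price
#' identity into
#' \deqn{\Delta\bar x = \frac{\mathrm{var}(x_{se})}{\bar w}
#'       \Big(\sum_k r_k b_k - c\Big),}
#' so `identity_residual` is zero to numerical precision and
#' \eqn{\sum_k r_k b_k > c} exactly when cooperativeness increases: this
#' version of Hamilton's rule cannot be violated, for *any* linear
#' specification — even though the individual `b`, `c` values are
#' specification-dependent.  The scale factor `var(x_se)/mean(w)`
#' (population moments) is stored explicitly as `factor`.
#'
#' @inheritParams ols_fit
#' @return A list of class `"hr_regression"`: `spec`, `c`, `b` (named per
#'   class), `r` (named per class), `delta_xbar`, `predicted_delta`,
#'   `identity_residual`, `factor`, `coefficients`, `linear`.
#' @export
regression_hr <- function(records, spec = hr_spec("I")) {
  if (pop_cov(records$x_se, records$x_se) <= 0)
    stop("relatedness is undefined: own cooperativeness has zero variance")
  cf <- ols_fit(records, spec)
  design <- build_design(records, spec)
  cost <- -cf[["x_se"]]
  b <- cf[spec$classes]
  r <- vapply(spec$classes, function(cl)
    pop_cov(design[[cl]], design$x_se) / pop_cov(design$x_se, design$x_se),
    0)
  w <- records$w
  delta_xbar <- sum(w * records$x_se) / sum(w) - mean(records$x_se)
  fac <- pop_cov(design$x_se, design$x_se) / mean(w)
  predicted <- fac * (sum(r * b) - cost)
  structure(list(spec = spec, c = cost, b = b, r = r,
                 delta_xbar = delta_xbar, predicted_delta = predicted,
                 identity_residual = delta_xbar - predicted, factor = fac,
                 coefficients = cf, linear = is_linear_spec(spec)),
            class = "hr_regression")
}

#' @export
print.hr_regression <- function(x, ...) {
  cat(sprintf("Regression Hamilton's rule (specification %s%s)\n",
              x$spec$id, if (x$linear) "" else ", non-linear terms present"))
  cat(sprintf("  c = %.6g\n", x$c))
  for (cl in names(x$b))
    cat(sprintf("  %s: b = %.6g, r = %.6g\n", cl, x$b[[cl]], x$r[[cl]]))
  cat(sprintf("  sum(r b) - c = %.6g\n", sum(x$r * x$b) - x$c))
  cat(sprintf("  delta_xbar = %.6g (identity residual %.2e)\n",
              x$delta_xbar, x$identity_residual))
  if (!x$linear)
    cat("  note: the Price/OLS identity is only guaranteed for linear",
        "specifications\n")
  invisible(x)
}

#' Nested F-test for non-linearity of the fitness function
#'
#' Compares a base (typically linear) specification against an extended
#' specification that nests it, by the standard nested-model F statistic.
#' Rejecting linearity is a precondition for observing genuine violations of
#' the counterfactual Hamilton's rule: with a linear fitness function the
#' rule coincides with the direction of selection for every population
#' structure.
#'
#' @inheritParams ols_fit
#' @param base_spec,extended_spec [hr_spec()] objects; `extended_spec` must
#'   strictly nest `base_spec`.
#' @param alpha Significance level for the verdict.
#' @return A list of class `"hr_nltest"`: `F`, `df1`, `df2`, `p_value`,
#'   `alpha`, `verdict` (`"linear adequate"` or `"non-linearity
#'   detected"`).
#' @export
nonlinearity_test <- function(records, base_spec = hr_spec("II"),
                              extended_spec = hr_spec("III"),
                              alpha = 0.05) {
  bt <- spec_terms(base_spec)
  et <- spec_terms(extended_spec)
  if (!all(bt %in% et))
    stop("extended_spec must nest base_spec")
  if (setequal(bt, et))
    stop("extended_spec adds no terms to base_spec; F is undefined")
  db <- build_design(records, base_spec)
  de <- build_design(records, extended_spec)
  fit_b <- stats::lm(w ~ ., data = db)
  fit_e <- stats::lm(w ~ ., data = de)
  if (stats::df.residual(fit_e) < 1L)
    stop("insufficient residual degrees of freedom for the extended model")
  an <- stats::anova(fit_b, fit_e)
  Fst <- an$F[2L]
  pval <- an$`Pr(>F)`[2L]
  structure(list(F = Fst, df1 = an$Df[2L], df2 = an$Res.Df[2L],
                 p_value = pval, alpha = alpha,
                 verdict = if (pval < alpha) "non-linearity detected"
                 else "linear adequate"),
            class = "hr_nltest")
}

#' @export
print.hr_nltest <- function(x, ...) {
  cat(sprintf("Non-linearity F-test: F(%d, %d) = %.4g, p = %.4g -> %s\n",
              x$df1, x$df2, x$F, x$p_value, x$verdict))
  invisible(x)
}

#' Simulate an individual-level social population
#'
#' Generates individual records of the kind an empirical test of Hamilton's
#' rule would collect: a binary own trait, partner traits for a sibling and
#' a cousin class (correlated with the focal trait through a
#' copy-with-probability-r mechanism, so the phenotypic relatedness of each
#' class is r in expectation), and fitness equal to a linear combination of
#' the traits plus Gaussian noise — with optional interaction and quadratic
#' terms for power studies.
#'
#' @param n Number of individuals.
#' @param p_coop Frequency of the cooperative trait.
#' @param r_sib,r_cou Pedigree relatedness of the sibling and cousin
#'   classes.
#' @param n_sib,n_cou Number of partners per class.
#' @param beta_se,beta_sib,beta_cou Linear fitness effects (of own trait and
#'   of each class's mean trait).
#' @param beta_int Coefficient of the own-by-sibling interaction.
#' @param beta_quad Coefficient of the squared sibling mean.
#' @param base_w Baseline fitness (kept high enough that fitness stays
#'   positive).
#' @param sd_w Standard deviation of the fitness noise.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return A data.frame with columns `id`, `x_se`, `w`, `sib_1..`, `cou_1..`.
#' @export
simulate_social_population <- function(n = 200L, p_coop = 0.5, r_sib = 0.5,
                                       r_cou = 0.125, n_sib = 2L,
                                       n_cou = 2L, beta_se = -0.5,
                                       beta_sib = 2, beta_cou = 0.5,
                                       beta_int = 0, beta_quad = 0,
                                       base_w = 5, sd_w = 1, seed = NULL) {
  gen <- function() {
    x <- stats::rbinom(n, 1L, p_coop)
    partner <- function(r, k) {
      m <- matrix(stats::rbinom(n * k, 1L, p_coop), n, k)
      copy <- matrix(stats::runif(n * k) < r, n, k)
      m[copy] <- rep(x, k)[copy]
      m
    }
    sib <- partner(r_sib, n_sib)
    cou <- partner(r_cou, n_cou)
    sib_m <- rowMeans(sib)
    cou_m <- rowMeans(cou)
    w <- base_w + beta_se * x + beta_sib * sib_m + beta_cou * cou_m +
      beta_int * x * sib_m + beta_quad * sib_m^2 +
      stats::rnorm(n, sd = sd_w)
    out <- data.frame(id = seq_len(n), x_se = x, w = w)
    colnames(sib) <- paste0("sib_", seq_len(n_sib))
    colnames(cou) <- paste0("cou_", seq_len(n_cou))
    cbind(out, sib, cou)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Read / write individual records as TSV
#'
#' Columns: `id`, `x_se`, `w`, then partner-trait columns named
#' `<class>_<k>` (e.g. `sib_1`, `sib_2`, `cou_1`).
#'
#' @param path File path.
#' @return `read_records_tsv()` returns the records data.frame.
#' @export
read_records_tsv <- function(path) {
  rec <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("x_se", "w") %in% names(rec)))
    stop("records TSV must have columns x_se and w")
  rec
}

#' @rdname read_records_tsv
#' @param records Records data.frame.
#' @export
write_records_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Rejection rate of the non-linearity test under simulation
#'
#' Repeatedly simulates populations with [simulate_social_population()] and
#' applies [nonlinearity_test()].  With `beta_int = 0` the truth is linear
#' and the rejection rate estimates the type-I error (which should sit at
#' `alpha`); with a non-zero interaction it estimates power.
#'
#' @param reps Number of replicate populations.
#' @param n Individuals per population.
#' @param beta_int Interaction effect size in the generating model.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [simulate_social_population()].
#' @return A list: `rejection_rate`, `reps`, `mc_se` (binomial Monte-Carlo
#'   standard error).
#' @export
nonlinearity_power <- function(reps = 1000L, n = 200L, beta_int = 0,
                               alpha = 0.05, seed = 1L, ...) {
  rej <- with_seed(seed, {
    vapply(seq_len(reps), function(k) {
      rec <- simulate_social_population(n = n, beta_int = beta_int, ...)
      nonlinearity_test(rec, hr_spec("II"), hr_spec("III"),
                        alpha = alpha)$p_value < alpha
    }, TRUE)
  })
  rate <- mean(rej)
  list(rejection_rate = rate, reps = reps,
       mc_se = sqrt(rate * (1 - rate) / reps))
}

#' Spurious violations of Hamilton's rule from relatedness estimation
#'
#' With costs and benefits estimated by OLS, Hamilton's rule evaluated with
#' the *phenotypic* relatedness estimator cov(x_se, x_si)/var(x_se) holds by
#' construction in every sample.  Empirical studies, however, often plug in
#' an independent (pedigree or marker-based) relatedness instead.  In small
#' samples the phenotypic estimator scatters around the pedigree value, so
#' the two evaluations of rb - c can end up on opposite sides of zero — an
#' *apparent* violation that is purely a sampling artefact.  This simulation
#' measures how often that happens as a function of sample size.
#'
#' @param seed Integer seed.
#' @param sample_sizes Vector of numbers of sibling pairs.
#' @param true_r Pedigree relatedness of the simulated sibling pairs.
#' @param effect_b,effect_c True benefit and cost in the linear fitness
#'   function.
#' @param reps Replicates per sample size (>= 100).
#' @param p_coop Trait frequency.
#' @param base_w,sd_w Fitness baseline and noise standard deviation.
#' @return A data.frame with columns `sample_size`, `reps`,
#'   `disagreement_rate` (fraction of replicates where the two evaluations
#'   of rb - c differ in sign), `mc_se`.
#' @export
spurious_violation_sim <- function(seed, sample_sizes = c(20L, 80L, 320L),
                                   true_r = 0.5, effect_b = 0.3,
                                   effect_c = 0.05, reps = 1000L,
                                   p_coop = 0.5, base_w = 2, sd_w = 1) {
  if (reps < 100L) stop("reps must be at least 100")
  one_rep <- function(n) {
    repeat {
      x <- stats::rbinom(n, 1L, p_coop)
      y <- ifelse(stats::runif(n) < true_r, x,
                  stats::rbinom(n, 1L, p_coop))
      vx <- pop_cov(x, x)
      vy <- pop_cov(y, y)
      cxy <- pop_cov(x, y)
      det <- vx * vy - cxy^2
      if (vx > 0 && det > 1e-12) break
    }
    w <- base_w + effect_b * y - effect_c * x + stats::rnorm(n, sd = sd_w)
    cxw <- pop_cov(x, w)
    cyw <- pop_cov(y, w)
    beta_x <- (vy * cxw - cxy * cyw) / det
    beta_y <- (vx * cyw - cxy * cxw) / det
    b_hat <- beta_y
    c_hat <- -beta_x
    r_phen <- cxy / vx
    sign(r_phen * b_hat - c_hat) != sign(true_r * b_hat - c_hat)
  }
  with_seed(seed, {
    rows <- lapply(sample_sizes, function(n) {
      dis <- mean(vapply(seq_len(reps), function(k) one_rep(n), TRUE))
      data.frame(sample_size = n, reps = reps, disagreement_rate = dis,
                 mc_se = sqrt(dis * (1 - dis) / reps))
    })
    do.call(rbind, rows)
  })
}
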