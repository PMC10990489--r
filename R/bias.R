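# Ligand-bias coefficients from dose-response fit parameters:
# delta-delta-log10 of relative activities (Etop/EC50) with error
# propagation and summary-statistic significance tests.

as_fit_pars <- function(fit) {
  if (inherits(fit, "hill_fit")) {
    fit <- list(etop = fit$etop, ec50 = fit$ec50, se_etop = fit$se_etop,
                se_ec50 = fit$se_ec50)
  }
  stopifnot(all(c("etop", "ec50") %in% names(fit)))
  if (is.null(fit$se_etop)) fit$se_etop <- 0
  if (is.null(fit$se_ec50)) fit$se_ec50 <- 0
  if (!is.finite(fit$etop) || !is.finite(fit$ec50) ||
      fit$etop <= 0 || fit$ec50 <= 0) {
    stop("Hill fit parameters must be positive and finite", call. = FALSE)
  }
  fit
}

#' Propagate standard errors through a scalar function
#'
#' Three methods are supported. `functional`: perturb each parameter one at
#' a time by its SE (one-sided, positive) and sum the squared changes of
#' `f`, `SE = sqrt(sum_i (f(..., x_i + se_i, ...) - f(x))^2)`. `derivative`:
#' first-order propagation with numerical partial derivatives,
#' `SE = sqrt(sum_i (df/dx_i * se_i)^2)`. `montecarlo`: draw independent
#' normal parameters and take the SD of `f` over draws. `symmetric` is the
#' functional variant with centred perturbations `(f(x+se) - f(x-se))/2`.
#'
#' @param f function taking a numeric vector of length `length(values)`.
#' @param values parameter values.
#' @param ses parameter standard errors (same length, >= 0).
#' @param method one of "functional", "derivative", "montecarlo",
#'   "symmetric".
#' @param n_draws Monte Carlo sample size (default 1e5).
#' @param seed seed for the Monte Carlo method (default 1).
#' @return the propagated standard error of `f(values)`.
#' @examples
#' propagate_error(function(x) log10(x), 10, 1)  # log10(1.1) = 0.0414
#' @export
propagate_error <- function(f, values, ses,
                            method = c("functional", "derivative",
                                       "montecarlo", "symmetric"),
                            n_draws = 1e5, seed = 1L) {
  method <- match.arg(method)
  values <- as.numeric(values)
  ses <- as.numeric(ses)
  stopifnot(length(values) == length(ses), all(ses >= 0))
  f0 <- suppressWarnings(f(values))
  if (!is.finite(f0)) stop("f undefined at the central values", call. = FALSE)
  k <- length(values)
  eval_pert <- function(i, delta) {
    v <- values
    v[i] <- v[i] + delta
    fv <- suppressWarnings(f(v))
    if (!is.finite(fv)) {
      stop(sprintf("f undefined when perturbing parameter %d", i),
           call. = FALSE)
    }
    fv
  }
  if (method == "functional") {
    d <- vapply(seq_len(k),
                function(i) if (ses[i] == 0) 0 else
                  eval_pert(i, ses[i]) - f0, numeric(1))
    sqrt(sum(d^2))
  } else if (method == "symmetric") {
    d <- vapply(seq_len(k),
                function(i) if (ses[i] == 0) 0 else
                  (eval_pert(i, ses[i]) - eval_pert(i, -ses[i])) / 2,
                numeric(1))
    sqrt(sum(d^2))
  } else if (method == "derivative") {
    d <- vapply(seq_len(k), function(i) {
      if (ses[i] == 0) return(0)
      h <- 1e-6 * max(abs(values[i]), 1e-300)
      grad <- (eval_pert(i, h) - eval_pert(i, -h)) / (2 * h)
      grad * ses[i]
    }, numeric(1))
    sqrt(sum(d^2))
  } else {
    with_seed(seed, {
      draws <- matrix(stats::rnorm(n_draws * k,
                                   mean = rep(values, each = n_draws),
                                   sd = rep(ses, each = n_draws)),
                      nrow = n_draws)
      vals <- apply(draws, 1L, function(v) {
        fv <- tryCatch(suppressWarnings(f(v)),
                       error = function(e) NA_real_)
        if (is.finite(fv)) fv else NA_real_
      })
      stats::sd(vals, na.rm = TRUE)
    })
  }
}

#' Per-ligand transduction coefficient beta-prime
#'
#' `beta' = log10[(Etop_num / EC50_num) * (EC50_den / Etop_den)]`: the log10
#' ratio of the ligand's relative activities (Etop/EC50) for the numerator
#' response versus the denominator response. The SE is propagated from the
#' four fit SEs.
#'
#' @param fit_num,fit_den `hill_fit` objects or lists with `etop`, `ec50`,
#'   `se_etop`, `se_ec50` -- the same ligand's fits for the two responses.
#' @param method error-propagation method, see [propagate_error()].
#' @return list with `beta_prime`, `se`.
#' @export
beta_prime <- function(fit_num, fit_den, method = "functional") {
  fn <- as_fit_pars(fit_num)
  fd <- as_fit_pars(fit_den)
  vals <- c(fn$etop, fn$ec50, fd$etop, fd$ec50)
  ses <- c(fn$se_etop, fn$se_ec50, fd$se_etop, fd$se_ec50)
  f <- function(p) log10((p[1] / p[2]) * (p[4] / p[3]))
  list(beta_prime = f(vals),
       se = propagate_error(f, vals, ses, method = method))
}

#' Ligand-bias coefficient beta against a reference ligand
#'
#' `beta = beta'(ligand) - beta'(reference)`: the delta-delta-log10 of
#' relative activities across two responses and two ligands. beta = 0 means
#' both ligands engage the two responses in the same proportion; beta != 0
#' means the ligand is biased toward (or against) the numerator response
#' relative to the reference. The SE combines all eight fit parameter
#' uncertainties in a single propagation.
#'
#' @param ligand_num,ligand_den the ligand's fits for the numerator and
#'   denominator responses.
#' @param reference_num,reference_den the reference ligand's fits for the
#'   same two responses (same order).
#' @param method error-propagation method, see [propagate_error()].
#' @param labels optional named list/vector (`ligand`, `reference`,
#'   `response_num`, `response_den`) carried into the result.
#' @return object of class `bias_result`: list with `beta`, `se`,
#'   `beta_prime_ligand` (+ `se_beta_prime_ligand`), `beta_prime_reference`
#'   (+ `se_beta_prime_reference`), `method`, and the labels.
#' @export
bias_coefficient <- function(ligand_num, ligand_den, reference_num,
                             reference_den, method = "functional",
                             labels = NULL) {
  l_n <- as_fit_pars(ligand_num)
  l_d <- as_fit_pars(ligand_den)
  r_n <- as_fit_pars(reference_num)
  r_d <- as_fit_pars(reference_den)
  vals <- c(l_n$etop, l_n$ec50, l_d$etop, l_d$ec50,
            r_n$etop, r_n$ec50, r_d$etop, r_d$ec50)
  ses <- c(l_n$se_etop, l_n$se_ec50, l_d$se_etop, l_d$se_ec50,
           r_n$se_etop, r_n$se_ec50, r_d$se_etop, r_d$se_ec50)
  f <- function(p) {
    log10((p[1] / p[2]) * (p[4] / p[3])) -
      log10((p[5] / p[6]) * (p[8] / p[7]))
  }
  bl <- beta_prime(ligand_num, ligand_den, method = method)
  br <- beta_prime(reference_num, reference_den, method = method)
  out <- list(beta = f(vals),
              se = propagate_error(f, vals, ses, method = method),
              beta_prime_ligand = bl$beta_prime,
              se_beta_prime_ligand = bl$se,
              beta_prime_reference = br$beta_prime,
              se_beta_prime_reference = br$se,
              method = method,
              ligand = labels$ligand %||% NA_character_,
              reference = labels$reference %||% NA_character_,
              response_num = labels$response_num %||% NA_character_,
              response_den = labels$response_den %||% NA_character_)
  class(out) <- "bias_result"
  out
}

#' @export
print.bias_result <- function(x, ...) {
  cat(sprintf("bias coefficient beta = %.4f +/- %.4f (%s propagation)\n",
              x$beta, x$se, x$method))
  if (!is.na(x$ligand)) {
    cat(sprintf("  %s vs %s; responses %s / %s\n", x$ligand, x$reference,
                x$response_num, x$response_den))
  }
  cat(sprintf("  beta' ligand = %.4f +/- %.4f; beta' reference = %.4f +/- %.4f\n",
              x$beta_prime_ligand, x$se_beta_prime_ligand,
              x$beta_prime_reference, x$se_beta_prime_reference))
  invisible(x)
}

#' One-way ANOVA reconstructed from group summary statistics
#'
#' Computes the textbook one-way ANOVA F test from per-group (mean, SEM, n)
#' without raw data: the between-group sum of squares from the means and
#' the within-group sum of squares from `sem^2 * n * (n - 1)` (since
#' `SEM^2 = s^2 / n`).
#'
#' @param means group means.
#' @param sems group standard errors of the mean (> 0).
#' @param ns group sizes (each >= 2).
#' @return list with `F`, `p`, `df1`, `df2`, `ss_between`, `ss_within`.
#' @export
anova_summary <- function(means, sems, ns) {
  means <- as.numeric(means)
  sems <- as.numeric(sems)
  ns <- as.integer(ns)
  k <- length(means)
  stopifnot(length(sems) == k, length(ns) == k)
  if (k < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(ns < 2L)) stop("every group needs n >= 2", call. = FALSE)
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(sems^2 * ns * (ns - 1L))
  df1 <- k - 1L
  df2 <- n_tot - k
  if (ssw == 0) {
    f_stat <- if (ssb == 0) 0 else Inf
  } else {
    f_stat <- (ssb / df1) / (ssw / df2)
  }
  list(F = f_stat, p = stats::pf(f_stat, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ss_between = ssb, ss_within = ssw)
}

#' Compare the slopes of two linear dose trends
#'
#' Fits ordinary least-squares lines to the two series and tests the slope
#' difference with a pooled-variance two-sided t-test
#' (df = n1 + n2 - 4). Used for near-linear readouts such as viability or
#' caspase activity versus ligand concentration.
#'
#' @param x1,y1 first series (>= 3 points).
#' @param x2,y2 second series (>= 3 points).
#' @return list with `t`, `p`, `df`, `slope1`, `slope2`, `se_diff`.
#' @export
compare_linear_slopes <- function(x1, y1, x2, y2) {
  chk <- function(x, y, lab) {
    if (length(x) < 3L || length(x) != length(y)) {
      stop(sprintf("series %s needs >= 3 (x, y) pairs", lab), call. = FALSE)
    }
    if (stats::var(x) == 0) {
      stop(sprintf("series %s has no spread in x", lab), call. = FALSE)
    }
  }
  chk(x1, y1, "1")
  chk(x2, y2, "2")
  f1 <- stats::lm(y1 ~ x1)
  f2 <- stats::lm(y2 ~ x2)
  b1 <- stats::coef(f1)[[2]]
  b2 <- stats::coef(f2)[[2]]
  rss <- sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2)
  df <- length(x1) + length(x2) - 4L
  sp2 <- rss / df
  sxx1 <- sum((x1 - mean(x1))^2)
  sxx2 <- sum((x2 - mean(x2))^2)
  se <- sqrt(sp2 * (1 / sxx1 + 1 / sxx2))
  t_stat <- if (se == 0) 0 else (b1 - b2) / se
  list(t = t_stat, p = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE),
       df = df, slope1 = b1, slope2 = b2, se_diff = se)
}
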