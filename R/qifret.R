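# QI-FRET analysis: intrinsic FRET of constitutive receptor dimers from
# per-vesicle FRET efficiency, donor and acceptor concentrations, and the
# fluorophore separation distance from the Foerster equation.

#' Acceptor fraction of a vesicle
#'
#' @param donor_conc,acceptor_conc receptor concentrations (any consistent
#'   units, both >= 0, not both zero). Vectorized.
#' @return `acceptor / (donor + acceptor)` in `[0, 1]`.
#' @examples
#' acceptor_fraction(100, 100)  # 0.5
#' @export
acceptor_fraction <- function(donor_conc, acceptor_conc) {
  if (any(donor_conc < 0) || any(acceptor_conc < 0)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  tot <- donor_conc + acceptor_conc
  if (any(tot <= 0)) {
    stop("donor + acceptor must be positive", call. = FALSE)
  }
  acceptor_conc / tot
}

#' Per-vesicle intrinsic FRET for constitutive dimers
#'
#' In the constitutive-dimer regime (FRET independent of receptor
#' concentration) the measured efficiency relates to the intrinsic FRET of
#' the donor/acceptor-labeled dimer by `E = E_tilde * x_A`, so
#' `E_tilde = E / x_A`. Vesicles with an acceptor fraction at or below
#' `xa_min` are excluded (dividing by a tiny x_A amplifies noise without
#' bound) and flagged with a reason.
#'
#' @param records data.frame with columns `donor_conc`, `acceptor_conc`,
#'   `E` (and optionally `vesicle_id`).
#' @param xa_min minimum acceptor fraction for inclusion (default 0.1).
#' @return the table with added columns `xA`, `E_tilde`, `included`
#'   (logical) and `exclusion_reason`; attribute `n_excluded`.
#' @export
intrinsic_fret <- function(records, xa_min = 0.1) {
  need <- c("donor_conc", "acceptor_conc", "E")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("vesicle table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records$xA <- acceptor_fraction(records$donor_conc,
                                  records$acceptor_conc)
  records$included <- records$xA > xa_min
  records$exclusion_reason <- ifelse(records$included, "",
                                     sprintf("xA <= %g", xa_min))
  records$E_tilde <- ifelse(records$included, records$E / records$xA,
                            NA_real_)
  attr(records, "n_excluded") <- sum(!records$included)
  records
}

#' Gaussian fit of the per-vesicle intrinsic-FRET histogram
#'
#' Histograms the intrinsic FRET values, normalizes to a maximum of 1, and
#' fits a Gaussian; its mean is the condition's intrinsic FRET and the SE
#' of the mean comes from the fit. Values outside `[0, 1.2]` are retained
#' for histogramming (they are noise, not errors).
#'
#' @param values per-vesicle intrinsic FRET values (>= 50).
#' @param bin_width histogram bin width; `NULL` for Freedman-Diaconis.
#' @return a `gaussian_fit` object; `m` is the intrinsic FRET estimate and
#'   `se_m` its standard error.
#' @export
fit_intrinsic_histogram <- function(values, bin_width = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 50L) {
    stop("need at least 50 vesicles", call. = FALSE)
  }
  fit <- fit_gaussian_histogram(values, bin_width = bin_width,
                                n_cells = length(values))
  if (!fit$converged) warning("intrinsic-FRET Gaussian fit did not converge",
                              call. = FALSE)
  fit
}

#' Fluorophore separation distance from intrinsic FRET
#'
#' Inverts the Foerster relation `E_tilde = 1 / (1 + (d/R0)^6)` (valid
#' under free rotation of the fluorophores):
#' `d = R0 * ((1 - E_tilde) / E_tilde)^(1/6)`.
#'
#' @param e_tilde intrinsic FRET in (0, 1). Vectorized.
#' @param r0 Foerster radius of the dye pair in Angstrom (default 53.1,
#'   eYFP/mCherry).
#' @return distance in Angstrom.
#' @examples
#' separation_distance(0.5)  # equals R0
#' @export
separation_distance <- function(e_tilde, r0 = 53.1) {
  if (any(e_tilde <= 0 | e_tilde >= 1)) {
    stop("intrinsic FRET must lie strictly in (0, 1)", call. = FALSE)
  }
  if (r0 <= 0) stop("r0 must be positive", call. = FALSE)
  r0 * ((1 - e_tilde) / e_tilde)^(1 / 6)
}

#' Intrinsic FRET from fluorophore separation distance
#'
#' The forward Foerster relation, the inverse of [separation_distance()].
#'
#' @param d distance in Angstrom (> 0). Vectorized.
#' @param r0 Foerster radius in Angstrom.
#' @return intrinsic FRET in (0, 1).
#' @export
fret_from_distance <- function(d, r0 = 53.1) {
  if (any(d <= 0)) stop("distance must be positive", call. = FALSE)
  if (r0 <= 0) stop("r0 must be positive", call. = FALSE)
  1 / (1 + (d / r0)^6)
}

#' Test whether FRET is independent of receptor concentration
#'
#' Regresses measured E on total receptor concentration. A slope that is
#' not significantly different from zero (t-test, alpha = 0.05) is the
#' signature of constitutive dimers: FRET then depends only on the acceptor
#' fraction, not on expression level.
#'
#' @param records vesicle table with `donor_conc`, `acceptor_conc`, `E`.
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `slope`, `se`, `t`, `p`, `constitutive` (logical).
#' @export
check_concentration_independence <- function(records, alpha = 0.05) {
  tot <- records$donor_conc + records$acceptor_conc
  if (length(tot) < 20L) stop("need at least 20 vesicles", call. = FALSE)
  if (max(tot) < 3 * min(tot)) {
    stop("insufficient concentration spread (need >= 3-fold range)",
         call. = FALSE)
  }
  fit <- stats::lm(records$E ~ tot)
  cf <- suppressWarnings(summary(fit)$coefficients)
  slope <- cf[2, "Estimate"]
  se <- cf[2, "Std. Error"]
  t_stat <- cf[2, "t value"]
  p <- cf[2, "Pr(>|t|)"]
  if (!is.finite(t_stat)) {
    # degenerate exact fit: a zero slope is perfectly constitutive
    t_stat <- if (abs(slope) < .Machine$double.eps^0.5) 0 else Inf
    p <- stats::pt(abs(t_stat), fit$df.residual, lower.tail = FALSE) * 2
  }
  list(slope = slope, se = se, t = t_stat, p = p,
       constitutive = p >= alpha)
}

#' Full QI-FRET summary for one condition
#'
#' Computes per-vesicle intrinsic FRET, fits the histogram Gaussian, and
#' converts the mean intrinsic FRET to a fluorophore separation distance
#' with its SE propagated by the functional method.
#'
#' @param records vesicle table (`donor_conc`, `acceptor_conc`, `E`).
#' @param r0 Foerster radius in Angstrom (default 53.1).
#' @param xa_min acceptor-fraction cutoff (default 0.1).
#' @param bin_width histogram bin width (default Freedman-Diaconis).
#' @return list with `n_vesicles`, `n_excluded`, `e_tilde_mean`,
#'   `se_e_tilde`, `distance_A`, `se_distance_A`, `r0_A`, `gaussian`
#'   (the fit), and `concentration_check`.
#' @export
summarize_fret <- function(records, r0 = 53.1, xa_min = 0.1,
                           bin_width = NULL) {
  rec <- intrinsic_fret(records, xa_min = xa_min)
  et <- rec$E_tilde[rec$included]
  fit <- fit_intrinsic_histogram(et, bin_width = bin_width)
  m <- fit$m
  d <- if (m > 0 && m < 1) separation_distance(m, r0) else NA_real_
  se_d <- if (is.finite(d)) {
    propagate_error(function(p) separation_distance(p[1], r0), m, fit$se_m)
  } else NA_real_
  conc_check <- tryCatch(check_concentration_independence(records),
                         error = function(e) NULL)
  list(n_vesicles = sum(rec$included),
       n_excluded = attr(rec, "n_excluded"),
       e_tilde_mean = m, se_e_tilde = fit$se_m,
       distance_A = d, se_distance_A = se_d, r0_A = r0,
       gaussian = fit, concentration_check = conc_check)
}
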