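# Dose-response analysis of western-blot band intensities: within-gel and
# global (gluing-gel) scaling, loss transform, truncation and Hill fitting.

check_dose_table <- function(tab) {
  need <- c("gel_id", "ligand", "conc", "intensity")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("dose-response table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(tab$conc < 0)) stop("negative concentrations", call. = FALSE)
  if (any(!is.finite(tab$intensity))) {
    stop("non-finite intensities", call. = FALSE)
  }
  invisible(tab)
}

#' Scale each gel's dose-response curve to a maximum of 1
#'
#' Every gel yields one dose-response curve; each is divided by its own
#' maximum band intensity so that within-gel relative responses become
#' comparable across gels with different exposure/loading.
#'
#' @param tab data.frame with columns `gel_id`, `ligand`, `conc`
#'   (molar), `intensity`; extra columns (e.g. `response`) pass through.
#' @return the same table with `intensity` rescaled per gel (and per
#'   `response`/`ligand` if present) and attribute `scale_state =
#'   "within_gel"`.
#' @examples
#' tab <- data.frame(gel_id = 1, ligand = "A", conc = c(0, 1, 10),
#'                   intensity = c(200, 500, 1000))
#' scale_within_gel(tab)$intensity  # 0.2 0.5 1.0
#' @export
scale_within_gel <- function(tab) {
  check_dose_table(tab)
  keys <- interaction(tab$gel_id, tab$ligand,
                      if ("response" %in% names(tab)) tab$response else "",
                      drop = TRUE)
  for (k in levels(keys)) {
    i <- keys == k
    mx <- max(tab$intensity[i])
    if (mx <= 0) {
      stop("gel with all-zero intensities cannot be scaled", call. = FALSE)
    }
    tab$intensity[i] <- tab$intensity[i] / mx
  }
  attr(tab, "scale_state") <- "within_gel"
  tab
}

#' Average replicate gels and renormalize the mean curve to a maximum of 1
#'
#' Groups within-gel-scaled intensities by concentration (per ligand and
#' response), computes mean and SEM across gels, and rescales so the largest
#' mean is 1 (SEMs are scaled by the same factor). Concentration grids must
#' agree across gels up to `align_tol` relative tolerance; concentrations
#' within tolerance are merged onto their common median.
#'
#' @param tab within-gel-scaled table from [scale_within_gel()].
#' @param align_tol relative tolerance for merging near-identical
#'   concentrations across gels (default 0.01).
#' @return data.frame with columns (`response`,) `ligand`, `conc`, `mean`,
#'   `sem`, `n`; attribute `scale_state = "averaged"`. With a single gel a
#'   warning is raised and `sem` is `NA`.
#' @export
average_replicates <- function(tab, align_tol = 0.01) {
  check_dose_table(tab)
  has_resp <- "response" %in% names(tab)
  grp <- interaction(if (has_resp) tab$response else "", tab$ligand,
                     drop = TRUE)
  out <- lapply(levels(grp), function(g) {
    d <- tab[grp == g, , drop = FALSE]
    d$conc <- align_concentrations(d$conc, align_tol)
    agg_m <- tapply(d$intensity, d$conc, mean)
    agg_s <- tapply(d$intensity, d$conc, stats::sd)
    agg_n <- tapply(d$intensity, d$conc, length)
    if (all(agg_n == 1L)) {
      warning("single gel: SEM undefined", call. = FALSE)
    }
    conc <- as.numeric(names(agg_m))
    o <- order(conc)
    res <- data.frame(ligand = d$ligand[1], conc = conc[o],
                      mean = as.numeric(agg_m)[o],
                      sem = as.numeric(agg_s)[o] / sqrt(as.numeric(agg_n)[o]),
                      n = as.integer(agg_n)[o])
    if (has_resp) res <- cbind(response = d$response[1], res,
                               stringsAsFactors = FALSE)
    top <- max(res$mean)
    if (top <= 0) stop("all-zero averaged curve", call. = FALSE)
    res$mean <- res$mean / top
    res$sem <- res$sem / top
    res
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "scale_state") <- "averaged"
  out
}

align_concentrations <- function(conc, tol) {
  u <- sort(unique(conc))
  if (length(u) < 2L) return(conc)
  rel <- diff(u) / pmax(u[-length(u)], .Machine$double.xmin)
  grp <- cumsum(c(TRUE, rel > tol))
  med <- tapply(u, grp, stats::median)
  map <- stats::setNames(as.numeric(med)[grp], u)
  out <- map[as.character(conc)]
  names(out) <- NULL
  out
}

#' Place per-ligand averaged curves on one global scale via a gluing gel
#'
#' The gluing gel re-runs each ligand's maximal-response samples side by
#' side. Per-ligand scale coefficients are the glue-gel means divided by
#' the largest glue-gel mean, so the highest-intensity ligand (the full
#' agonist) keeps its maximum at 1 and partial agonists are scaled down.
#'
#' @param avg averaged table from [average_replicates()].
#' @param glue data.frame with columns `ligand`, `intensity` (>= 1 row per
#'   ligand; the protocol uses 3).
#' @return `avg` with `mean` and `sem` multiplied by the per-ligand
#'   coefficient; attributes `scale_state = "global"` and `glue_coefficients`
#'   (named vector).
#' @examples
#' avg <- data.frame(ligand = rep(c("A", "B"), each = 2),
#'                   conc = rep(c(1e-9, 1e-8), 2),
#'                   mean = c(0.5, 1, 0.5, 1), sem = 0.05, n = 3)
#' glue <- data.frame(ligand = rep(c("A", "B"), each = 3),
#'                    intensity = c(0.8, 0.8, 0.8, 1, 1, 1))
#' glue_scale(avg, glue)
#' @export
glue_scale <- function(avg, glue) {
  stopifnot(all(c("ligand", "conc", "mean") %in% names(avg)),
            all(c("ligand", "intensity") %in% names(glue)))
  ligs <- unique(avg$ligand)
  miss <- setdiff(ligs, unique(glue$ligand))
  if (length(miss)) {
    stop("ligand(s) missing from gluing gel: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  gm <- tapply(glue$intensity, glue$ligand, mean)[ligs]
  gse <- tapply(glue$intensity, glue$ligand,
                function(x) if (length(x) > 1L) {
                  stats::sd(x) / sqrt(length(x))
                } else 0)[ligs]
  coef <- as.numeric(gm) / max(gm)
  names(coef) <- ligs
  # relative SE of each coefficient: quadrature of the ligand's and the
  # top ligand's glue-band relative SEs; the top ligand's own coefficient
  # is 1 by construction (self-division), SE 0
  rel <- as.numeric(gse) / as.numeric(gm)
  top <- which.max(gm)
  coef_rel_se <- sqrt(rel^2 + rel[top]^2)
  coef_rel_se[top] <- 0
  names(coef_rel_se) <- ligs
  i <- match(avg$ligand, ligs)
  avg$mean <- avg$mean * coef[i]
  if ("sem" %in% names(avg)) avg$sem <- avg$sem * coef[i]
  attr(avg, "scale_state") <- "global"
  attr(avg, "glue_coefficients") <- coef
  attr(avg, "glue_coefficient_rel_se") <- coef_rel_se
  avg
}

#' Convert an abundance curve into a loss-of-abundance curve
#'
#' For readouts where ligand causes loss of a species (receptor
#' downregulation, collagen type 2), the zero-ligand band is the largest:
#' the curve is rescaled so the zero-ligand mean is 1, then subtracted from
#' 1 so that loss is 0 at zero ligand and grows with dose.
#'
#' @param avg averaged table (columns `ligand`, `conc`, `mean`, optionally
#'   `sem`); must contain `conc == 0` rows for every ligand.
#' @return the table with `mean` replaced by loss values (`sem` scaled by
#'   the same baseline factor).
#' @examples
#' avg <- data.frame(ligand = "A", conc = c(0, 1e-9, 1e-8),
#'                   mean = c(1, 0.8, 0.6), sem = 0)
#' loss_transform(avg)$mean  # 0 0.2 0.4
#' @export
loss_transform <- function(avg) {
  stopifnot(all(c("ligand", "conc", "mean") %in% names(avg)))
  has_resp <- "response" %in% names(avg)
  grp <- interaction(if (has_resp) avg$response else "", avg$ligand,
                     drop = TRUE)
  for (g in levels(grp)) {
    i <- grp == g
    base_i <- i & avg$conc == 0
    if (!any(base_i)) {
      stop("missing zero-ligand baseline row", call. = FALSE)
    }
    v0 <- mean(avg$mean[base_i])
    if (v0 <= 0) stop("zero-ligand baseline is not positive", call. = FALSE)
    avg$mean[i] <- 1 - avg$mean[i] / v0
    if ("sem" %in% names(avg)) avg$sem[i] <- avg$sem[i] / v0
  }
  attr(avg, "scale_state") <- "loss"
  avg
}

#' Truncate a dose-response curve for hyperbolic fitting
#'
#' Some curves decline at high dose (e.g. FGF4-driven responses); only the
#' ascending portion is described by the rectangular hyperbola. The curve is
#' truncated at the highest concentration whose response is within 10% of
#' the maximum response value (y >= (1 - tol) * max(y)); all points at or
#' below that concentration are kept.
#'
#' @param conc strictly increasing concentration vector.
#' @param y response values, same length.
#' @param tol relative tolerance (default 0.1 -- "within 10% of the max").
#' @return integer indices of the kept prefix.
#' @examples
#' truncate_for_fit(1:5, c(0.2, 0.6, 1.0, 0.95, 0.7))  # 1:4
#' @export
truncate_for_fit <- function(conc, y, tol = 0.1) {
  if (length(conc) == 0L || length(conc) != length(y)) {
    stop("conc and y must be non-empty and of equal length", call. = FALSE)
  }
  if (is.unsorted(conc, strictly = TRUE)) {
    stop("conc must be strictly increasing", call. = FALSE)
  }
  cut <- max(which(y >= (1 - tol) * max(y)))
  seq_len(cut)
}

#' Fit a rectangular hyperbola (Hill equation with n = 1)
#'
#' Fits `y = x * Etop / (x + EC50)` by Levenberg-Marquardt least squares,
#' weighted by `1/sem^2` when SEMs are available. Points with `sem` of 0 or
#' `NA` receive the median weight of the curve (an exact zero SEM would get
#' infinite weight). Zero-concentration points are legitimate: the model
#' passes through the origin. The curve is truncated first with
#' [truncate_for_fit()] unless `truncate = FALSE`.
#'
#' For a weighted fit the supplied SEMs are treated as known measurement
#' errors: parameter standard errors are taken from the weighted-fit
#' covariance without the reduced chi-square factor, which keeps them
#' calibrated when the weights describe the true error structure. For an
#' unweighted fit the residual variance is estimated from the fit (the
#' standard `nls` summary). With `pool_sem = TRUE` the per-point SEMs are
#' replaced, for weighting, by a pooled relative error: a single
#' coefficient of variation estimated across the whole curve times each
#' point's response. Gel-blot errors scale with band intensity, and with
#' only ~3 replicate gels a per-point SEM is too noisy to invert into a
#' weight, so the pipeline ([fit_dose_response()]) pools by default.
#'
#' @param conc molar concentrations (sorted increasing or not; sorted
#'   internally).
#' @param y responses.
#' @param sem optional per-point SEMs for weighting.
#' @param truncate apply the 10% truncation rule first (default TRUE).
#' @param tol truncation tolerance passed to [truncate_for_fit()].
#' @param pool_sem replace per-point SEMs by a pooled relative error for
#'   weighting (default FALSE; the pipeline wrapper uses TRUE).
#' @return object of class `hill_fit`: list with `etop`, `ec50`, `se_etop`,
#'   `se_ec50`, `n_points`, `truncation_conc`, `converged`, `weights_used`,
#'   and the fitted `nls` model as `fit`.
#' @examples
#' x <- 10^seq(-10.5, -7.5, by = 0.5)
#' f <- fit_hill(x, x * 1 / (x + 1e-9))
#' c(f$etop, f$ec50)
#' @export
fit_hill <- function(conc, y, sem = NULL, truncate = TRUE, tol = 0.1,
                     pool_sem = FALSE) {
  o <- order(conc)
  conc <- conc[o]
  y <- y[o]
  if (!is.null(sem)) sem <- sem[o]
  if (truncate) {
    keep <- truncate_for_fit(conc, y, tol = tol)
    conc <- conc[keep]
    y <- y[keep]
    if (!is.null(sem)) sem <- sem[keep]
  }
  if (sum(conc > 0) < 3L) {
    stop("need at least 3 distinct nonzero concentrations after truncation",
         call. = FALSE)
  }
  weights_used <- !is.null(sem) && any(is.finite(sem) & sem > 0)
  if (weights_used && pool_sem) {
    ok <- is.finite(sem) & sem > 0 & y > 0
    cv <- sqrt(mean((sem[ok] / y[ok])^2))
    sem <- pmax(cv * abs(y), cv * max(abs(y)) * 1e-6)
  }
  if (weights_used) {
    w <- 1 / sem^2
    bad <- !is.finite(w) | sem <= 0
    if (any(bad)) w[bad] <- stats::median(w[!bad])
  } else {
    w <- rep(1, length(y))
  }
  etop0 <- max(y)
  pos <- conc > 0
  ec0 <- conc[pos][which.min(abs(y[pos] - etop0 / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ conc * Etop / (conc + EC50),
      start = list(Etop = etop0, EC50 = ec0),
      lower = c(Etop = .Machine$double.xmin, EC50 = .Machine$double.xmin),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 1000)),
    error = function(e) NULL)
  out <- list(n_points = length(y), truncation_conc = max(conc),
              weights_used = weights_used, conc = conc, y = y)
  if (is.null(fit)) {
    out <- c(out, list(etop = NA_real_, ec50 = NA_real_, se_etop = NA_real_,
                       se_ec50 = NA_real_, converged = FALSE, fit = NULL))
  } else {
    sm <- summary(fit)
    cf <- sm$coefficients
    # with supplied weights the SEMs are known errors: drop the estimated
    # residual-scale factor from the reported standard errors
    fac <- if (weights_used) 1 / sm$sigma else 1
    out$etop <- cf["Etop", "Estimate"]
    out$ec50 <- cf["EC50", "Estimate"]
    out$se_etop <- cf["Etop", "Std. Error"] * fac
    out$se_ec50 <- cf["EC50", "Std. Error"] * fac
    out$converged <- fit$convInfo$isConv
    out$fit <- fit
  }
  class(out) <- "hill_fit"
  out
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit (n = 1): Etop = %.4g (SE %.3g), EC50 = %.4g M (SE %.3g)\n",
              x$etop, x$se_etop, x$ec50, x$se_ec50))
  cat(sprintf("  %d points, truncated at %.3g M, weighted: %s, converged: %s\n",
              x$n_points, x$truncation_conc, x$weights_used, x$converged))
  invisible(x)
}

#' Fit every (response, ligand) curve of a globally scaled table
#'
#' Weighting pools the per-point SEMs into a single relative error per
#' curve (`pool_sem = TRUE`, see [fit_hill()]). If the table carries
#' gluing-gel coefficient uncertainties (attribute
#' `glue_coefficient_rel_se`, set by [glue_scale()]), the global-scale
#' uncertainty is added in quadrature to each Etop standard error --
#' multiplying a whole curve by an uncertain coefficient shifts Etop
#' coherently, which the point-wise fit covariance cannot see.
#'
#' @param avg table from [glue_scale()] (or [average_replicates()] /
#'   [loss_transform()]): columns (`response`,) `ligand`, `conc`, `mean`,
#'   `sem`.
#' @param truncate,tol,pool_sem passed to [fit_hill()].
#' @return data.frame with one row per (response, ligand): `etop`,
#'   `se_etop`, `ec50`, `se_ec50`, `n_points`, `truncation_conc`,
#'   `converged`.
#' @export
fit_dose_response <- function(avg, truncate = TRUE, tol = 0.1,
                              pool_sem = TRUE) {
  has_resp <- "response" %in% names(avg)
  coef_rel_se <- attr(avg, "glue_coefficient_rel_se")
  grp <- interaction(if (has_resp) avg$response else "", avg$ligand,
                     drop = TRUE)
  rows <- lapply(levels(grp), function(g) {
    d <- avg[grp == g, , drop = FALSE]
    f <- fit_hill(d$conc, d$mean, sem = d$sem, truncate = truncate,
                  tol = tol, pool_sem = pool_sem)
    if (!is.null(coef_rel_se) && d$ligand[1] %in% names(coef_rel_se) &&
        is.finite(f$se_etop)) {
      f$se_etop <- sqrt(f$se_etop^2 +
                          (f$etop * coef_rel_se[[d$ligand[1]]])^2)
    }
    cbind(if (has_resp) data.frame(response = d$response[1],
                                   stringsAsFactors = FALSE),
          data.frame(ligand = d$ligand[1], etop = f$etop,
                     se_etop = f$se_etop, ec50 = f$ec50,
                     se_ec50 = f$se_ec50, n_points = f$n_points,
                     truncation_conc = f$truncation_conc,
                     converged = f$converged))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
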