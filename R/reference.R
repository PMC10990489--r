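# Bundled reference best-fit dose-response parameters for FGF4, FGF8 and
# FGF9 acting on FGFR1, and the standard bias map computed from them.

#' Published best-fit dose-response parameters for FGF4/FGF8/FGF9
#'
#' Best-fit (Etop, EC50) pairs with standard errors for the phosphorylation
#' readouts (FGFR1 Y653/654, Y766, PLCgamma, FRS2), FGFR1 downregulation,
#' and the chondrocyte functional readouts (growth arrest, collagen type 2
#' loss), for the three ligands. These are the reference inputs for the
#' bias map: all bias coefficients are derived from them alone.
#'
#' @return data.frame with columns `response`, `ligand`, `ec50`, `se_ec50`
#'   (molar), `etop`, `se_etop` (globally scaled response units).
#' @export
fgfr1_fit_parameters <- function() {
  tab <- rbind(
    c("pY653/654",       "FGF4", 4.77e-10, 0.42e-10, 0.95, 0.03),
    c("pY653/654",       "FGF8", 1.04e-08, 0.23e-08, 1.11, 0.07),
    c("pY653/654",       "FGF9", 2.09e-09, 0.31e-09, 0.70, 0.02),
    c("pY766",           "FGF4", 5.84e-10, 1.26e-10, 0.76, 0.05),
    c("pY766",           "FGF8", 1.42e-08, 0.25e-08, 1.16, 0.07),
    c("pY766",           "FGF9", 1.94e-09, 0.71e-09, 0.56, 0.05),
    c("pPLCg",           "FGF4", 7.98e-11, 2.15e-11, 0.80, 0.04),
    c("pPLCg",           "FGF8", 1.05e-09, 0.23e-09, 0.99, 0.03),
    c("pPLCg",           "FGF9", 2.05e-10, 0.40e-10, 0.62, 0.02),
    c("pFRS2",           "FGF4", 3.42e-10, 0.70e-10, 0.94, 0.06),
    c("pFRS2",           "FGF8", 1.62e-09, 0.29e-09, 0.98, 0.03),
    c("pFRS2",           "FGF9", 1.65e-09, 0.15e-09, 0.52, 0.01),
    c("downregulation",  "FGF4", 7.34e-10, 4.54e-10, 0.27, 0.04),
    c("downregulation",  "FGF8", 1.39e-08, 0.39e-08, 0.63, 0.05),
    c("downregulation",  "FGF9", 6.80e-09, 2.08e-09, 0.42, 0.02),
    c("growth_arrest",   "FGF4", 2.59e-12, 1.10e-13, 0.99, 0.004),
    c("growth_arrest",   "FGF8", 1.60e-09, 2.30e-10, 1.14, 0.04),
    c("growth_arrest",   "FGF9", 5.89e-11, 8.50e-12, 0.95, 0.004),
    c("collagen2_loss",  "FGF4", 1.24e-11, 2.79e-12, 1.02, 0.01),
    c("collagen2_loss",  "FGF8", 8.51e-11, 2.86e-11, 0.77, 0.03),
    c("collagen2_loss",  "FGF9", 5.67e-11, 2.89e-11, 0.86, 0.06))
  data.frame(response = tab[, 1], ligand = tab[, 2],
             ec50 = as.numeric(tab[, 3]), se_ec50 = as.numeric(tab[, 4]),
             etop = as.numeric(tab[, 5]), se_etop = as.numeric(tab[, 6]),
             stringsAsFactors = FALSE)
}

#' Standard FGFR1 bias map
#'
#' The set of (ligand, reference, numerator response, denominator response)
#' comparisons evaluated against the reference ligand FGF8. Numerator and
#' denominator are explicit: for the phosphorylation and downregulation
#' pairs the numerator is the second-listed response of the conventional
#' row label (e.g. row "pY653/654 vs pFRS2" has numerator pFRS2); for the
#' chondrocyte functional pair the numerator is collagen type 2 loss. This
#' pinning reproduces the published signs, which are not recoverable from
#' the row labels alone.
#'
#' @return data.frame with columns `ligand`, `reference`, `response_num`,
#'   `response_den`, `label`.
#' @export
fgfr1_bias_map <- function() {
  pairs <- rbind(
    c("pY766",          "pY653/654",     "pY653/654 vs pY766"),
    c("pPLCg",          "pY653/654",     "pY653/654 vs pPLCg"),
    c("pFRS2",          "pY653/654",     "pY653/654 vs pFRS2"),
    c("pPLCg",          "pY766",         "pY766 vs pPLCg"),
    c("pFRS2",          "pY766",         "pY766 vs pFRS2"),
    c("pFRS2",          "pPLCg",         "pPLCg vs pFRS2"),
    c("downregulation", "pY653/654",     "pY653/654 vs downregulation"),
    c("downregulation", "pY766",         "pY766 vs downregulation"),
    c("downregulation", "pPLCg",         "pPLCg vs downregulation"),
    c("downregulation", "pFRS2",         "pFRS2 vs downregulation"),
    c("collagen2_loss", "growth_arrest", "collagen2_loss vs growth_arrest"))
  out <- expand.grid(ligand = c("FGF4", "FGF9"), row = seq_len(nrow(pairs)),
                     stringsAsFactors = FALSE)
  data.frame(ligand = out$ligand, reference = "FGF8",
             response_num = pairs[out$row, 1],
             response_den = pairs[out$row, 2],
             label = pairs[out$row, 3], stringsAsFactors = FALSE)
}

#' Compute a bias map from a table of dose-response fits
#'
#' For every row of `map`, looks up the four (ligand/reference x
#' numerator/denominator response) fits in `fits` and computes the bias
#' coefficient with propagated SE.
#'
#' @param fits data.frame with columns `response`, `ligand`, `etop`,
#'   `se_etop`, `ec50`, `se_ec50` (as from [fit_dose_response()] or
#'   [fgfr1_fit_parameters()]).
#' @param map data.frame with columns `ligand`, `reference`,
#'   `response_num`, `response_den` (as from [fgfr1_bias_map()]).
#' @param method error-propagation method, see [propagate_error()].
#' @return data.frame: the map plus `beta`, `se`, `beta_prime_ligand`,
#'   `se_beta_prime_ligand`, `beta_prime_reference`,
#'   `se_beta_prime_reference`, `method`.
#' @export
compute_bias_map <- function(fits, map, method = "functional") {
  get_fit <- function(resp, lig) {
    i <- which(fits$response == resp & fits$ligand == lig)
    if (length(i) != 1L) {
      stop(sprintf("no unique fit for response '%s', ligand '%s'",
                   resp, lig), call. = FALSE)
    }
    as.list(fits[i, c("etop", "ec50", "se_etop", "se_ec50")])
  }
  rows <- lapply(seq_len(nrow(map)), function(r) {
    m <- map[r, ]
    b <- bias_coefficient(
      ligand_num = get_fit(m$response_num, m$ligand),
      ligand_den = get_fit(m$response_den, m$ligand),
      reference_num = get_fit(m$response_num, m$reference),
      reference_den = get_fit(m$response_den, m$reference),
      method = method,
      labels = list(ligand = m$ligand, reference = m$reference,
                    response_num = m$response_num,
                    response_den = m$response_den))
    cbind(m, data.frame(beta = b$beta, se = b$se,
                        beta_prime_ligand = b$beta_prime_ligand,
                        se_beta_prime_ligand = b$se_beta_prime_ligand,
                        beta_prime_reference = b$beta_prime_reference,
                        se_beta_prime_reference = b$se_beta_prime_reference,
                        method = method))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reproduce the full bias map from the bundled reference parameters
#'
#' Runs [compute_bias_map()] on [fgfr1_fit_parameters()] with
#' [fgfr1_bias_map()]: the complete set of FGF4-vs-FGF8 and FGF9-vs-FGF8
#' bias coefficients with propagated uncertainties, derived from the
#' published fit parameters alone.
#'
#' @param method error-propagation method (default "functional").
#' @return data.frame, see [compute_bias_map()].
#' @examples
#' head(reproduce_bias_map())
#' @export
reproduce_bias_map <- function(method = "functional") {
  compute_bias_map(fgfr1_fit_parameters(), fgfr1_bias_map(),
                   method = method)
}
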