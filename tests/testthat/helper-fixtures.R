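# Shared fixtures for the test suite. Everything is generated in code.

# Reference best-fit parameters for a (response, ligand) pair, as a plain
# list usable by beta_prime()/bias_coefficient().
ref_fit <- function(response, ligand) {
  tab <- fgfr1_fit_parameters()
  i <- which(tab$response == response & tab$ligand == ligand)
  as.list(tab[i, c("etop", "ec50", "se_etop", "se_ec50")])
}

# Three-ligand truth set for one phosphorylation response, used by the
# recovery simulations (relative efficacies and molar potencies).
phospho_truth <- function() {
  data.frame(response = "pY653/654",
             ligand = c("FGF4", "FGF8", "FGF9"),
             etop = c(0.95, 1.11, 0.70),
             ec50 = c(4.77e-10, 1.04e-8, 2.09e-9),
             stringsAsFactors = FALSE)
}

# Standard 8-point concentration grid (zero + 7 log-spaced points, molar).
std_grid <- function() c(0, 10^seq(-10.5, -7.5, by = 0.5))

# Expected Etop in globally scaled units: the gluing-gel chain divides all
# curves by the full agonist's response at the top concentration.
scaled_etop_truth <- function(truth, grid) {
  xmax <- max(grid)
  r_top <- truth$etop * xmax / (xmax + truth$ec50)
  truth$etop / max(r_top)
}

# Run the full scaling chain (within-gel -> average -> glue) for one
# simulated experiment, per response.
run_scaling_chain <- function(sim) {
  do.call(rbind, lapply(unique(sim$table$response), function(r) {
    avg <- average_replicates(
      scale_within_gel(sim$table[sim$table$response == r, , drop = FALSE]))
    fit_dose_response(
      glue_scale(avg, sim$glue[sim$glue$response == r, , drop = FALSE]))
  }))
}
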