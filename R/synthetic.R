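# Seeded synthetic-data generators with the statistical structure the
# analysis chain assumes: photon-counting membrane images for brightness
# analysis, replicate gel band-intensity tables with hidden per-gel scales,
# and per-vesicle FRET records for constitutive dimers.

#' Specification for a synthetic photon-counting membrane image
#'
#' @param field_size image side length in pixels.
#' @param density receptor density, receptors per square micron (the
#'   experiments bracket 100-200).
#' @param oligomer_sizes named numeric vector: names are oligomer sizes k,
#'   values the probability that a randomly chosen oligomer has size k
#'   (must sum to 1). `c("1" = 1)` is a pure monomer population,
#'   `c("2" = 1)` a pure dimer population.
#' @param counts_per_fluorophore mean detector counts contributed by one
#'   fluorophore in one pixel.
#' @param pixel_area_um2 area of one pixel in square microns.
#' @param background mean background counts per pixel (Poisson rate).
#' @return validated list of class `fif_sim_spec`.
#' @export
fif_sim_spec <- function(field_size = 60L, density = 150,
                         oligomer_sizes = c("1" = 1),
                         counts_per_fluorophore = 5,
                         pixel_area_um2 = 0.0256, background = 0) {
  p <- as.numeric(oligomer_sizes)
  k <- as.integer(names(oligomer_sizes))
  if (any(is.na(k)) || any(k < 1L)) {
    stop("oligomer sizes must be named by positive integers", call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-8 || any(p < 0)) {
    stop("oligomer size probabilities must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (density < 0 || background < 0 || counts_per_fluorophore <= 0 ||
      pixel_area_um2 <= 0 || field_size < 1L) {
    stop("invalid simulation spec", call. = FALSE)
  }
  structure(list(field_size = as.integer(field_size), density = density,
                 sizes = k, probs = p,
                 counts_per_fluorophore = counts_per_fluorophore,
                 pixel_area_um2 = pixel_area_um2, background = background),
            class = "fif_sim_spec")
}

#' Simulate one photon-counting membrane image
#'
#' Oligomers are placed uniformly at random on the pixel grid; an oligomer
#' of size k contributes k fluorophores at its pixel. Photon counts are
#' Poisson with rate `counts_per_fluorophore * local fluorophores +
#' background`. The number of oligomers is chosen so the expected
#' fluorophore density matches `density` regardless of the oligomer-size
#' mix, so brightness comparisons across specs are at equal fluorophore
#' (receptor) density.
#'
#' @param spec a [fif_sim_spec()].
#' @param seed integer seed; identical (spec, seed) give identical images.
#' @return list with `image` (matrix of counts) and `truth` (fluorophore
#'   count, oligomer count, mean oligomer size).
#' @export
simulate_fif_image <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fif_sim_spec"))
  area <- spec$field_size^2 * spec$pixel_area_um2
  n_fluor_target <- spec$density * area
  mean_k <- sum(spec$sizes * spec$probs)
  n_olig <- round(n_fluor_target / mean_k)
  max_rate <- spec$counts_per_fluorophore * n_fluor_target + spec$background
  if (!is.finite(max_rate) || max_rate > 1e12) {
    stop("density too high: Poisson rate overflow", call. = FALSE)
  }
  with_seed(seed, {
    npx <- spec$field_size^2
    fluor <- numeric(npx)
    if (n_olig > 0) {
      sizes <- spec$sizes[sample.int(length(spec$sizes), n_olig,
                                     replace = TRUE, prob = spec$probs)]
      pos <- sample.int(npx, n_olig, replace = TRUE)
      fluor <- as.numeric(tapply(sizes, factor(pos, levels = seq_len(npx)),
                                 sum))
      fluor[is.na(fluor)] <- 0
    }
    rate <- spec$counts_per_fluorophore * fluor + spec$background
    img <- matrix(stats::rpois(npx, rate), spec$field_size, spec$field_size)
    list(image = img,
         truth = list(n_fluorophores = sum(fluor), n_oligomers = n_olig,
                      mean_oligomer_size = mean_k))
  })
}

#' Simulate a brightness sample over many cells
#'
#' Draws `n_cells` independent images from `spec` and pools the per-ROI
#' brightness values into one [brightness_sample()].
#'
#' @param spec a [fif_sim_spec()].
#' @param n_cells number of simulated cells (images).
#' @param roi_size region size in pixels.
#' @param condition label for the sample.
#' @param seed integer seed.
#' @return a `brightness_sample`.
#' @export
simulate_fif_condition <- function(spec, n_cells = 100L, roi_size = 15L,
                                   condition = "synthetic", seed = 1L) {
  with_seed(seed, {
    eps <- unlist(lapply(seq_len(n_cells), function(i) {
      sim <- simulate_fif_image(spec, seed = NULL)
      image_brightness(sim$image, roi_size = roi_size)
    }))
    brightness_sample(eps, condition = condition, n_cells = n_cells)
  })
}

#' Specification for synthetic dose-response gels
#'
#' @param truth data.frame with columns `response`, `ligand`, `etop`,
#'   `ec50` (molar): the true relative efficacies and potencies.
#' @param conc concentration grid in molar, including 0 if desired.
#' @param n_gels gels (independent replicates) per (response, ligand).
#' @param gel_scale_sdlog SD of the hidden per-gel multiplicative scale on
#'   the log scale (scales are lognormal with median 1).
#' @param noise_sd fractional (multiplicative Gaussian) band-intensity
#'   noise; the blots report 5-10% average error, default 0.07.
#' @param glue_noise_sd fractional noise on gluing-gel bands.
#' @param n_glue gluing-gel replicates per ligand (protocol: 3).
#' @param decline_conc optional concentration above which a biphasic
#'   (FGF4-like) multiplicative decline sets in; `NULL` for none.
#' @param decline_strength hyperbolic decline scale: the response is
#'   multiplied by `1 / (1 + (x / decline_conc))` beyond `decline_conc`.
#' @return validated list of class `dose_sim_spec`.
#' @export
dose_sim_spec <- function(truth, conc, n_gels = 3L, gel_scale_sdlog = 0.3,
                          noise_sd = 0.07, glue_noise_sd = 0.07,
                          n_glue = 3L, decline_conc = NULL,
                          decline_strength = 1) {
  stopifnot(all(c("response", "ligand", "etop", "ec50") %in% names(truth)))
  if (any(truth$etop <= 0) || any(truth$ec50 <= 0)) {
    stop("true Etop and EC50 must be positive", call. = FALSE)
  }
  if (noise_sd < 0 || glue_noise_sd < 0 || gel_scale_sdlog < 0) {
    stop("noise parameters must be non-negative", call. = FALSE)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(truth = truth, conc = sort(unique(conc)),
                 n_gels = as.integer(n_gels),
                 gel_scale_sdlog = gel_scale_sdlog, noise_sd = noise_sd,
                 glue_noise_sd = glue_noise_sd, n_glue = as.integer(n_glue),
                 decline_conc = decline_conc,
                 decline_strength = decline_strength),
            class = "dose_sim_spec")
}

hill_response <- function(x, etop, ec50) x * etop / (x + ec50)

#' Simulate raw band-intensity tables and a gluing gel
#'
#' Band intensity = hidden gel scale x Hill response x (1 + N(0,
#' noise_sd)), clipped at 0. The gluing gel re-runs each ligand's maximal
#' sample on one common gel: its expected intensity is the ligand's true
#' response at the top concentration, again with multiplicative noise.
#' With a biphasic spec, responses above `decline_conc` are multiplied by
#' a declining factor, emulating the loss of response at high ligand seen
#' for FGF4-like curves.
#'
#' @param spec a [dose_sim_spec()].
#' @param seed integer seed.
#' @return list with `table` (columns response, ligand, gel_id, conc,
#'   intensity), `glue` (per response: ligand, replicate, intensity), and
#'   `truth` (the spec's truth plus per-gel scales).
#' @export
simulate_dose_response <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "dose_sim_spec"))
  with_seed(seed, {
    rows <- list()
    glue_rows <- list()
    scales <- list()
    x_top <- max(spec$conc)
    for (r in seq_len(nrow(spec$truth))) {
      tr <- spec$truth[r, ]
      resp <- hill_response(spec$conc, tr$etop, tr$ec50)
      if (!is.null(spec$decline_conc)) {
        high <- spec$conc > spec$decline_conc
        fac <- rep(1, length(resp))
        fac[high] <- 1 / (1 + spec$decline_strength *
                            (spec$conc[high] / spec$decline_conc - 1))
        resp <- resp * fac
      }
      for (g in seq_len(spec$n_gels)) {
        s_g <- stats::rlnorm(1, 0, spec$gel_scale_sdlog)
        scales[[length(scales) + 1L]] <-
          data.frame(response = tr$response, ligand = tr$ligand,
                     gel_id = g, scale = s_g)
        intensity <- pmax(0, s_g * resp *
                            (1 + stats::rnorm(length(resp), 0,
                                              spec$noise_sd)))
        rows[[length(rows) + 1L]] <-
          data.frame(response = tr$response, ligand = tr$ligand,
                     gel_id = g, conc = spec$conc, intensity = intensity)
      }
      top_resp <- hill_response(x_top, tr$etop, tr$ec50)
      glue_rows[[length(glue_rows) + 1L]] <-
        data.frame(response = tr$response, ligand = tr$ligand,
                   replicate = seq_len(spec$n_glue),
                   intensity = pmax(0, top_resp *
                                      (1 + stats::rnorm(spec$n_glue, 0,
                                                        spec$glue_noise_sd))))
    }
    list(table = do.call(rbind, rows), glue = do.call(rbind, glue_rows),
         truth = list(parameters = spec$truth,
                      gel_scales = do.call(rbind, scales)))
  })
}

#' Specification for synthetic QI-FRET vesicle records
#'
#' @param n_vesicles number of vesicles.
#' @param e_tilde true intrinsic FRET of the dimer, in (0, 1).
#' @param conc_range 2-vector: donor and acceptor concentrations are drawn
#'   log-uniformly in this range (receptors per area, arbitrary units).
#' @param noise_sd additive Gaussian noise on the measured E.
#' @param conc_slope optional linear dependence of E on total
#'   concentration; 0 (the default) is the constitutive-dimer regime, a
#'   positive value mimics a monomer-dimer equilibrium.
#' @return validated list of class `fret_sim_spec`.
#' @export
fret_sim_spec <- function(n_vesicles = 300L, e_tilde = 0.42,
                          conc_range = c(50, 2000), noise_sd = 0.05,
                          conc_slope = 0) {
  if (e_tilde <= 0 || e_tilde >= 1) {
    stop("e_tilde must lie in (0, 1)", call. = FALSE)
  }
  if (n_vesicles < 1L || noise_sd < 0 || any(conc_range <= 0) ||
      conc_range[2] < conc_range[1]) {
    stop("invalid FRET simulation spec", call. = FALSE)
  }
  structure(list(n_vesicles = as.integer(n_vesicles), e_tilde = e_tilde,
                 conc_range = conc_range, noise_sd = noise_sd,
                 conc_slope = conc_slope),
            class = "fret_sim_spec")
}

#' Simulate per-vesicle FRET records
#'
#' Donor and acceptor concentrations are drawn log-uniformly; the measured
#' efficiency is `E = e_tilde * xA + conc_slope * total + N(0, noise_sd)`.
#'
#' @param spec a [fret_sim_spec()].
#' @param seed integer seed.
#' @return data.frame with `vesicle_id`, `donor_conc`, `acceptor_conc`,
#'   `E`; attribute `truth` holds the spec.
#' @export
simulate_vesicles <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "fret_sim_spec"))
  with_seed(seed, {
    lo <- log(spec$conc_range[1])
    hi <- log(spec$conc_range[2])
    donor <- exp(stats::runif(spec$n_vesicles, lo, hi))
    acceptor <- exp(stats::runif(spec$n_vesicles, lo, hi))
    xa <- acceptor / (donor + acceptor)
    e <- spec$e_tilde * xa + spec$conc_slope * (donor + acceptor) +
      stats::rnorm(spec$n_vesicles, 0, spec$noise_sd)
    out <- data.frame(vesicle_id = sprintf("v%04d",
                                           seq_len(spec$n_vesicles)),
                      donor_conc = donor, acceptor_conc = acceptor, E = e)
    attr(out, "truth") <- spec
    out
  })
}
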