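# End-to-end pipeline driver: runs the analysis stages from a single
# config (list or YAML file), writes intermediate CSVs, a machine-readable
# JSON summary and a run log.

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in order and writes every intermediate
#' table to `out_dir`, plus `summary.json` (machine readable) and
#' `run_log.txt` (versions, seed, parameters). Supported stages:
#' \describe{
#'   \item{fif}{Brightness analysis of TIFF images. Config block `fif`:
#'     `images` (directory with one subdirectory of single-channel TIFFs
#'     per condition; each image is one cell), `roi_size` (default 15),
#'     `bin_width` (optional).}
#'   \item{doseresponse}{Gel scaling and Hill fitting. Config block
#'     `doseresponse`: `data` (CSV: response, ligand, gel_id, conc,
#'     intensity), `glue` (CSV: response, ligand, intensity; optional),
#'     `loss_transform` (logical, default FALSE).}
#'   \item{bias}{Bias map from fits. Config block `bias`: `fits` (CSV;
#'     defaults to the doseresponse stage output, or the bundled reference
#'     parameters if `fits: "reference"`), `map` (CSV with ligand,
#'     reference, response_num, response_den; defaults to the standard
#'     map), `method` (error propagation, default "functional").}
#'   \item{qifret}{Intrinsic FRET summary. Config block `qifret`:
#'     `vesicles` (CSV: vesicle_id, donor_conc, acceptor_conc, E), `r0`
#'     (default 53.1), `xa_min` (default 0.1).}
#' }
#'
#' @param config a named list or the path of a YAML/JSON file. Must contain
#'   `stages` (character vector) and `out_dir`; `seed` (default 1) feeds
#'   any stochastic step.
#' @return invisible list of per-stage results (also serialized to
#'   `summary.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L) {
    stop("config must list at least one stage", call. = FALSE)
  }
  known <- c("fif", "doseresponse", "bias", "qifret")
  bad <- setdiff(stages, known)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must set out_dir", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L

  log_lines <- c(sprintf("fgfbias %s",
                         as.character(utils::packageVersion("fgfbias"))),
                 sprintf("R %s", R.version.string),
                 sprintf("seed: %s", seed),
                 sprintf("stages: %s", paste(stages, collapse = ", ")))
  results <- list()

  for (stage in stages) {
    res <- tryCatch(
      switch(stage,
             fif = stage_fif(config, out_dir),
             doseresponse = stage_doseresponse(config, out_dir),
             bias = stage_bias(config, out_dir, results),
             qifret = stage_qifret(config, out_dir)),
      error = function(e) {
        writeLines(c(log_lines, sprintf("FAILED at stage %s: %s", stage,
                                        conditionMessage(e))),
                   file.path(out_dir, "run_log.txt"))
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      })
    results[[stage]] <- res
    log_lines <- c(log_lines, sprintf("stage %s: ok", stage))
  }

  jsonlite::write_json(results, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(results)
}

stage_fif <- function(config, out_dir) {
  cfg <- config$fif %||% list()
  if (is.null(cfg$images)) stop("fif stage needs an images directory")
  roi_size <- cfg$roi_size %||% 15L
  conds <- list.dirs(cfg$images, recursive = FALSE)
  if (length(conds) == 0L) stop("no condition subdirectories found")
  eps_rows <- list()
  fits <- list()
  for (cd in conds) {
    files <- list.files(cd, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
    if (length(files) == 0L) next
    eps <- unlist(lapply(files, function(f) {
      image_brightness(read_fif_image(f), roi_size = roi_size)
    }))
    cond <- basename(cd)
    eps_rows[[cond]] <- data.frame(condition = cond,
                                   roi_index = seq_along(eps),
                                   epsilon = eps)
    sm <- brightness_sample(eps, condition = cond,
                            n_cells = length(files))
    fits[[cond]] <- fit_log_gaussian(sm, bin_width = cfg$bin_width)
  }
  eps_tab <- do.call(rbind, eps_rows)
  fit_tab <- brightness_fit_table(fits)
  utils::write.csv(eps_tab, file.path(out_dir, "fif_epsilon.csv"),
                   row.names = FALSE)
  utils::write.csv(fit_tab, file.path(out_dir, "fif_fits.csv"),
                   row.names = FALSE)
  fit_tab
}

stage_doseresponse <- function(config, out_dir) {
  cfg <- config$doseresponse %||% list()
  if (is.null(cfg$data)) stop("doseresponse stage needs a data CSV")
  tab <- utils::read.csv(cfg$data, stringsAsFactors = FALSE)
  tab <- scale_within_gel(tab)
  avg <- average_replicates(tab)
  if (!is.null(cfg$glue)) {
    glue <- utils::read.csv(cfg$glue, stringsAsFactors = FALSE)
    if ("response" %in% names(avg) && "response" %in% names(glue)) {
      avg <- do.call(rbind, lapply(unique(avg$response), function(r) {
        glue_scale(avg[avg$response == r, , drop = FALSE],
                   glue[glue$response == r, , drop = FALSE])
      }))
    } else {
      avg <- glue_scale(avg, glue)
    }
  }
  if (isTRUE(cfg$loss_transform)) avg <- loss_transform(avg)
  fits <- fit_dose_response(avg)
  utils::write.csv(avg, file.path(out_dir, "scaled_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(fits, file.path(out_dir, "dose_response_fits.csv"),
                   row.names = FALSE)
  fits
}

stage_bias <- function(config, out_dir, results) {
  cfg <- config$bias %||% list()
  fits <- if (is.null(cfg$fits)) {
    results$doseresponse %||%
      stop("bias stage needs fits (none produced upstream)")
  } else if (identical(cfg$fits, "reference")) {
    fgfr1_fit_parameters()
  } else {
    utils::read.csv(cfg$fits, stringsAsFactors = FALSE)
  }
  map <- if (is.null(cfg$map)) {
    fgfr1_bias_map()
  } else {
    utils::read.csv(cfg$map, stringsAsFactors = FALSE)
  }
  method <- cfg$method %||% "functional"
  bias <- compute_bias_map(fits, map, method = method)
  utils::write.csv(bias, file.path(out_dir, "bias_map.csv"),
                   row.names = FALSE)
  bias
}

stage_qifret <- function(config, out_dir) {
  cfg <- config$qifret %||% list()
  if (is.null(cfg$vesicles)) stop("qifret stage needs a vesicles CSV")
  rec <- utils::read.csv(cfg$vesicles, stringsAsFactors = FALSE)
  s <- summarize_fret(rec, r0 = cfg$r0 %||% 53.1,
                      xa_min = cfg$xa_min %||% 0.1,
                      bin_width = cfg$bin_width)
  out <- data.frame(n_vesicles = s$n_vesicles, n_excluded = s$n_excluded,
                    e_tilde_mean = s$e_tilde_mean,
                    se_e_tilde = s$se_e_tilde, distance_A = s$distance_A,
                    se_distance_A = s$se_distance_A, r0_A = s$r0_A)
  utils::write.csv(out, file.path(out_dir, "qifret_summary.csv"),
                   row.names = FALSE)
  out
}
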