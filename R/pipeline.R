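# YAML-configured pipeline tying the stages together:
# simulate -> reconstruct -> filter -> baseline -> evaluate.
# Physical quantities carry explicit unit suffixes in their key names
# (tc_s, current_ma, ...) because unit bugs are the dominant failure mode in
# physics pipelines. Unknown keys are rejected.

#' Default pipeline configuration
#'
#' @return Nested named list mirroring the YAML schema; see
#'   [validate_config()] for the accepted keys.
#' @export
default_config <- function() {
  list(
    phantom = list(
      n = 128L,
      fov_mm = 240,
      disc_radius_frac = 0.4,
      background_sigma_spm = 0.4,
      magnitude_background = 30,
      magnitude_inclusion = 4,
      magnitude_noise_std = 1
    ),
    acquisition = list(
      tc_s = 0.050,
      seed = 1L
    ),
    electrodes = list(
      current_ma = 10,
      width_mm = 80,
      thickness_mm = 80
    ),
    reconstruction = list(
      sigma_h_spm = NULL,  # NULL: use the phantom background
      eps_denominator = 1e-6
    ),
    filter = list(
      c_h = 1,
      c_eta = 4,
      eta_max = 6L,
      h_floor = NULL,  # NULL: 5% of the magnitude dynamic range
      snr_ref = 5
    ),
    baseline = list(
      alpha = 0.1,
      beta = 0.01,
      n_iter = 200L,
      grad_floor = 1e-8
    )
  )
}

config_schema <- function() {
  lapply(default_config(), names)
}

#' Validate a pipeline configuration
#'
#' Checks the block/key structure against the schema (unknown keys are
#' rejected by name), fills unset keys from [default_config()], and validates
#' units and ranges of the physical parameters.
#'
#' @param config Nested named list (e.g. from `yaml::read_yaml()`); missing
#'   blocks/keys take their defaults.
#' @return The completed, validated configuration.
#' @export
validate_config <- function(config = list()) {
  schema <- config_schema()
  if (is.null(config)) config <- list()
  unknown_blocks <- setdiff(names(config), names(schema))
  if (length(unknown_blocks)) {
    stop(sprintf("unknown config block(s): %s",
                 paste(unknown_blocks, collapse = ", ")), call. = FALSE)
  }
  full <- default_config()
  for (blk in names(config)) {
    unknown <- setdiff(names(config[[blk]]), schema[[blk]])
    if (length(unknown)) {
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    for (key in names(config[[blk]])) {
      full[[blk]][[key]] <- config[[blk]][[key]]
    }
  }
  need_pos <- list(
    c("phantom", "n"), c("phantom", "fov_mm"),
    c("phantom", "disc_radius_frac"), c("phantom", "background_sigma_spm"),
    c("phantom", "magnitude_background"), c("phantom", "magnitude_noise_std"),
    c("acquisition", "tc_s"),
    c("electrodes", "current_ma"), c("electrodes", "width_mm"),
    c("electrodes", "thickness_mm"),
    c("reconstruction", "eps_denominator"),
    c("filter", "c_h"), c("filter", "c_eta"), c("filter", "eta_max")
  )
  for (nk in need_pos) {
    val <- full[[nk[1]]][[nk[2]]]
    if (is.null(val) || !is.numeric(val) || length(val) != 1L ||
        !is.finite(val) || val <= 0) {
      stop(sprintf("config %s.%s must be a positive number", nk[1], nk[2]),
           call. = FALSE)
    }
  }
  if (is.null(full$acquisition$seed) ||
      !is.numeric(full$acquisition$seed)) {
    stop("config acquisition.seed must be an integer", call. = FALSE)
  }
  full
}

#' Run the MREIT pipeline
#'
#' Executes the requested stages on a synthetic phantom and writes every
#' product (NIfTI-1 + CSV per map, JSON reports, a provenance record echoing
#' the full configuration) into `outdir`. Reruns with the same configuration
#' are bit-identical; timestamped progress goes to `pipeline.log` only.
#'
#' @param config Pipeline configuration (validated via [validate_config()]).
#' @param outdir Output directory (created if needed).
#' @param stages Character vector among `"simulate"`, `"reconstruct"`,
#'   `"filter"`, `"baseline"`, `"evaluate"`; defaults to all, in order.
#' @param seed Optional override of `config$acquisition$seed`.
#' @param verbose Log to console as well as the log file.
#' @return Invisibly, the in-memory results of [run_phantom_experiment()]
#'   plus `baseline` and `report_file` entries.
#' @export
run_pipeline <- function(config = list(), outdir, stages = c(
                           "simulate", "reconstruct", "filter", "baseline",
                           "evaluate"),
                         seed = NULL, verbose = FALSE) {
  stages <- match.arg(stages, several.ok = TRUE)
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$acquisition$seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(outdir, "pipeline.log")
  log_line <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    if (verbose) message(msg)
  }
  run_stage <- function(name, expr) {
    log_line("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    log_line("stage %s: done", name)
    res
  }

  grid <- mreit_grid(cfg$phantom$n, fov = cfg$phantom$fov_mm * 1e-3)
  fov <- cfg$phantom$fov_mm * 1e-3
  phantom <- make_disc_phantom(
    grid,
    background_sigma = cfg$phantom$background_sigma_spm,
    inclusions = default_inclusions(fov, cfg$phantom$magnitude_inclusion),
    disc_radius = cfg$phantom$disc_radius_frac * fov,
    magnitude_background = cfg$phantom$magnitude_background,
    magnitude_noise_std = cfg$phantom$magnitude_noise_std
  )

  res <- run_stage("simulate+reconstruct+filter", run_phantom_experiment(
    seed = cfg$acquisition$seed,
    grid = grid,
    phantom = phantom,
    tc_s = cfg$acquisition$tc_s,
    current = cfg$electrodes$current_ma * 1e-3,
    electrode_width = cfg$electrodes$width_mm * 1e-3,
    thickness = cfg$electrodes$thickness_mm * 1e-3,
    sigma_h = cfg$reconstruction$sigma_h_spm,
    c_h = cfg$filter$c_h, c_eta = cfg$filter$c_eta,
    eta_max = cfg$filter$eta_max, h_floor = cfg$filter$h_floor,
    snr_ref = cfg$filter$snr_ref,
    eps_denominator = cfg$reconstruction$eps_denominator
  ))
  log_line("median SNR %.3g, median sd(Bz) %.3g T",
           stats::median(res$noise$snr[res$phantom$support]),
           stats::median(res$noise$values[res$phantom$support]))

  if ("simulate" %in% stages) {
    run_stage("write-simulate", {
      for (fmt in c("nii", "csv")) {
        write_image(res$phantom$sigma,
                    file.path(outdir, paste0("sigma_true.", fmt)))
        write_image(res$phantom$magnitude,
                    file.path(outdir, paste0("magnitude_true.", fmt)))
        write_image(res$magnitude_measured,
                    file.path(outdir, paste0("magnitude_measured.", fmt)))
        for (n in 1:2) {
          write_image(res$bz_true[[n]],
                      file.path(outdir, sprintf("bz_true_%d.%s", n, fmt)))
          write_image(res$bz_meas[[n]],
                      file.path(outdir, sprintf("bz_measured_%d.%s", n, fmt)))
        }
      }
      labels <- matrix(0, grid$n_rows, grid$n_cols)
      roi_names <- names(res$phantom$rois)
      for (k in seq_along(roi_names)) {
        labels[res$phantom$rois[[roi_names[k]]]$mask] <- k
      }
      write_image(labels, file.path(outdir, "roi_labels.csv"), grid = grid,
                  meta = list(labels = roi_names))
    })
  }
  if ("reconstruct" %in% stages) {
    run_stage("write-reconstruct", {
      for (fmt in c("nii", "csv")) {
        write_image(res$recon, file.path(outdir, paste0("sigma_recon.", fmt)),
                    meta = list(sigma_h_spm = res$ref$sigma_h,
                                eps_denominator =
                                  cfg$reconstruction$eps_denominator,
                                stencil = "central/one-sided, shared"))
      }
    })
  }
  if ("filter" %in% stages) {
    run_stage("write-filter", {
      for (fmt in c("nii", "csv")) {
        write_image(res$filtered,
                    file.path(outdir, paste0("sigma_filtered.", fmt)),
                    meta = cfg$filter[c("c_h", "c_eta", "eta_max")])
        write_image(res$params$h, file.path(outdir, paste0("h_map.", fmt)),
                    grid = grid)
        write_image(res$params$eta + 0,
                    file.path(outdir, paste0("eta_map.", fmt)), grid = grid)
      }
    })
  }
  baseline <- NULL
  if ("baseline" %in% stages) {
    baseline <- run_stage("baseline", reaction_diffusion(
      res$recon, alpha = cfg$baseline$alpha, beta = cfg$baseline$beta,
      n_iter = cfg$baseline$n_iter, grad_floor = cfg$baseline$grad_floor))
    for (fmt in c("nii", "csv")) {
      write_image(baseline, file.path(outdir, paste0("sigma_baseline.", fmt)),
                  meta = cfg$baseline)
    }
  }
  report_file <- NULL
  if ("evaluate" %in% stages) {
    run_stage("evaluate", {
      tab <- res$report$table
      report_file <- file.path(outdir, "variance_report.json")
      jsonlite::write_json(
        list(table = tab, mean_reduction_pct = res$report$mean_reduction_pct),
        report_file, auto_unbox = TRUE, digits = NA)
      txt <- utils::capture.output(print(res$report))
      writeLines(txt, file.path(outdir, "variance_report.txt"))
      log_line("mean V reduction %.1f%%", res$report$mean_reduction_pct)
    })
    report_file <- file.path(outdir, "variance_report.json")
  }

  prov <- list(package = "mreitfilter",
               version = as.character(utils::packageVersion("mreitfilter")),
               config = cfg, stages = stages)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(c(res, list(baseline = baseline, report_file = report_file,
                        config = cfg)))
}
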