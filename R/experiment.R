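#' Default experiment configuration
#'
#' The three-phenotype design of the assay: two highly invasive lines and
#' one non-invasive, cluster-forming line, three replicate chips each,
#' scored on days 1 and 2. The line names mark the configurations as
#' synthetic stand-ins calibrated to the corresponding phenotypes, not as
#' the cell lines themselves.
#'
#' @param seed experiment-level seed; per-chip seeds are derived from it.
#' @param n_chips replicate chips per arm (default 3).
#' @param n_cells agents per chip (default 400).
#' @return Config list for \code{\link{generate_experiment}}.
#' @export
default_experiment_config <- function(seed = 1L, n_chips = 3,
                                      n_cells = 400) {
  list(
    seed = as.integer(seed),
    geometry = list(),
    um_per_px = 1,
    n_cells = n_cells,
    steps_per_day = 24,
    ic50_uM = 1,
    clustering_radius_um = 150,
    arms = list(
      list(cell_line = "T24like", phenotype = "invasive",
           drift_um_per_step = 7, diffusion_um = 6,
           doses = 0, n_chips = n_chips, days = c(1, 2)),
      list(cell_line = "J82like", phenotype = "invasive",
           drift_um_per_step = 8, diffusion_um = 6,
           doses = 0, n_chips = n_chips, days = c(1, 2)),
      list(cell_line = "RT4like", phenotype = "non_invasive",
           drift_um_per_step = 0, diffusion_um = 2,
           doses = 0, n_chips = n_chips, days = c(1, 2))
    ),
    render = list(enabled = FALSE, psf_sigma_um = 4, snr = 20,
                  labeled_fraction = 1, peak = 1000, background = 100,
                  bits_per_sample = 16),
    out_dir = NULL,
    keep_states = FALSE
  )
}

#' Dose-response experiment configuration
#'
#' One invasive line treated with a migrastatic inhibitor at the assayed
#' doses 0, 1, 10 and 100 uM, three chips per dose, days 1 and 2.
#'
#' @inheritParams default_experiment_config
#' @param doses dose arms, uM.
#' @return Config list for \code{\link{generate_experiment}}.
#' @export
dose_experiment_config <- function(seed = 1L, n_chips = 3, n_cells = 400,
                                   doses = c(0, 1, 10, 100)) {
  cfg <- default_experiment_config(seed = seed, n_chips = n_chips,
                                   n_cells = n_cells)
  cfg$arms <- list(
    list(cell_line = "J82like", phenotype = "invasive",
         drift_um_per_step = 8, diffusion_um = 6,
         doses = doses, n_chips = n_chips, days = c(1, 2))
  )
  cfg
}

chip_seed <- function(seed, i) {
  # distinct, reproducible per-chip seeds within 32-bit integer range
  as.integer((as.numeric(seed) * 100003 + i * 7919) %% 2147483647L)
}

config_digest <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Generate a ground-truthed synthetic chip experiment
#'
#' Simulates every chip of every arm, scores the agent positions directly
#' on the acquisition grid (the ground truth — no rendering, noise or
#' segmentation involved), and optionally renders and writes one
#' fluorescence TIFF plus a JSON metadata sidecar per chip and day.
#' Determinism: the same config (including seed) reproduces trajectories,
#' scores and images bit-identically.
#'
#' @param config a config list, see \code{\link{default_experiment_config}}.
#' @return List: \code{scores} (ground-truth score data.frame, one row
#'   per chip and day), \code{table} (long format for the statistics
#'   functions), \code{files} (data.frame of written images, if any),
#'   \code{grid}, \code{effective_radius_um}, \code{digest}, and
#'   \code{states} (per-chip simulation states when
#'   \code{config$keep_states}).
#' @export
generate_experiment <- function(config = default_experiment_config()) {
  if (is.null(config$arms) || length(config$arms) == 0)
    stop("config must define at least one arm")
  for (arm in config$arms)
    for (fld in c("cell_line", "phenotype", "doses", "n_chips", "days"))
      if (is.null(arm[[fld]]))
        stop("arm is missing field '", fld, "'")
  geom <- do.call(build_geometry, config$geometry %||% list())
  grid <- acquisition_grid(geom, um_per_px = config$um_per_px %||% 1)
  rend <- config$render %||% list(enabled = FALSE)
  r_eff <- effective_blob_radius(rend$psf_sigma_um %||% 4)
  out_dir <- config$out_dir
  if (isTRUE(rend$enabled)) {
    if (is.null(out_dir)) stop("rendering requires config$out_dir")
    if (!dir.exists(out_dir)) {
      dir.create(out_dir, recursive = TRUE)
      message("created output directory ", out_dir)
    }
  }
  digest <- config_digest(config)

  scores <- list()
  files <- list()
  states_out <- list()
  idx <- 0L
  for (arm in config$arms) {
    for (dose in arm$doses) {
      for (chip in seq_len(arm$n_chips)) {
        idx <- idx + 1L
        chip_id <- sprintf("%s_dose%g_chip%d", arm$cell_line, dose, chip)
        params <- simulation_params(
          phenotype = arm$phenotype,
          drift_um_per_step = arm$drift_um_per_step,
          diffusion_um = arm$diffusion_um,
          steps_per_day = config$steps_per_day %||% 24,
          n_cells = config$n_cells %||% 400,
          clustering_radius_um = config$clustering_radius_um %||% 150,
          dose_uM = dose, ic50_uM = config$ic50_uM %||% 1,
          seed = chip_seed(config$seed %||% 1L, idx))
        sim <- simulate_chip(params, geom, max(arm$days))
        if (isTRUE(config$keep_states)) states_out[[chip_id]] <- sim
        for (day in arm$days) {
          st <- sim[[day + 1]]
          gt <- score_positions(st$positions, geom,
                                cell_radius_um = r_eff, grid = grid)
          scores[[length(scores) + 1]] <- data.frame(
            chip_id = chip_id, day = day, cell_line = arm$cell_line,
            dose_uM = dose, n_ipts_crossed = gt$n_ipts_crossed,
            max_distance_um = gt$max_distance_um,
            crossings = paste(as.integer(gt$crossings), collapse = ""))
          if (isTRUE(rend$enabled)) {
            set.seed(chip_seed(params$seed, 500 + day))
            rs <- render_state(st, grid = grid,
                               psf_sigma_um = rend$psf_sigma_um %||% 4,
                               snr = rend$snr %||% 20,
                               labeled_fraction = rend$labeled_fraction %||% 1,
                               peak = rend$peak %||% 1000,
                               background = rend$background %||% 100,
                               bits_per_sample = rend$bits_per_sample %||% 16)
            base <- file.path(out_dir, sprintf("%s_day%d", chip_id, day))
            write_tiff(rs$image$pixels, paste0(base, ".tif"),
                       bits_per_sample = rend$bits_per_sample %||% 16)
            meta <- list(chip_id = chip_id, day = day,
                         cell_line = arm$cell_line, dose_uM = dose,
                         modality = "fluorescence",
                         um_per_px = grid$um_per_px,
                         origin_px = grid$calibration$origin_px,
                         y_toward_upper = grid$calibration$y_toward_upper,
                         threshold = rs$threshold,
                         effective_radius_um = rs$effective_radius_um,
                         seed = params$seed, config_digest = digest,
                         package_version =
                           as.character(utils::packageVersion("bladderchip")))
            writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE,
                                        digits = NA),
                       paste0(base, ".json"))
            files[[length(files) + 1]] <- data.frame(
              chip_id = chip_id, day = day,
              tiff = paste0(base, ".tif"), sidecar = paste0(base, ".json"))
          }
        }
      }
    }
  }
  scores_df <- do.call(rbind, scores)
  res <- list(scores = scores_df,
              table = as_experiment_table(scores_df),
              files = if (length(files)) do.call(rbind, files) else NULL,
              grid = grid, geometry = geom,
              effective_radius_um = r_eff, digest = digest,
              states = if (isTRUE(config$keep_states)) states_out else NULL)
  if (!is.null(out_dir) && dir.exists(out_dir)) {
    utils::write.csv(scores_df,
                     file.path(out_dir, "ground_truth_scores.csv"),
                     row.names = FALSE)
    utils::write.csv(res$table,
                     file.path(out_dir, "experiment_table.csv"),
                     row.names = FALSE)
    geometry_json(geom, file.path(out_dir, "geometry.json"))
  }
  res
}
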