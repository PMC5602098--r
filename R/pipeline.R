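#' Configuration of an end-to-end pipeline run
#'
#' Bundles the survey generator configuration with the imagery, raster
#' and analysis options of [run_all()], and round-trips losslessly
#' through JSON so every run can store its resolved configuration next to
#' its outputs.
#'
#' @param seed Integer seed; the single source of randomness of the run.
#' @param generator A [generator_config()] (its seed is superseded by
#'   `seed`).
#' @param scene_width,scene_height Per-plot field-scene size, pixels. The
#'   defaults are deliberately below full drone resolution so a default
#'   run stays interactive; segmentation accuracy is resolution-invariant
#'   on these scenes.
#' @param pixel_size_cm Scene pixel size, cm.
#' @param contrast Scene colour contrast in \[0, 1\].
#' @param raster_noise_sd,raster_k SWIR raster noise level and cover
#'   attenuation, see [render_spectral_scene()].
#' @param ndti_mode Plot extraction mode, `"pixel"` or `"mean3"`.
#' @param write_images If `TRUE`, [run_all()] writes every scene PNG and
#'   the raster TIFF under the output directory (slower, larger).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L,
                       generator = generator_config(),
                       scene_width = 320L, scene_height = 240L,
                       pixel_size_cm = 0.27, contrast = 1,
                       raster_noise_sd = 0.15, raster_k = 0.4,
                       ndti_mode = c("pixel", "mean3"),
                       write_images = FALSE) {
  ndti_mode <- match.arg(ndti_mode)
  structure(list(seed = as.integer(seed), generator = generator,
                 scene_width = as.integer(scene_width),
                 scene_height = as.integer(scene_height),
                 pixel_size_cm = pixel_size_cm, contrast = contrast,
                 raster_noise_sd = raster_noise_sd, raster_k = raster_k,
                 ndti_mode = ndti_mode, write_images = write_images),
            class = "run_config")
}

#' Serialise / restore a run configuration as JSON
#'
#' Function-valued generator fields (marginals) are stored by name when
#' they are the defaults; custom marginal functions do not survive the
#' round trip and are rejected.
#'
#' @param config A [run_config()].
#' @param path JSON file path.
#' @return `read_run_config()` returns a `"run_config"`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  if (!identical(deparse(body(gen$marginals$lt)),
                 deparse(body(default_marginals()$lt)))) {
    stop("custom marginal functions cannot be serialised to JSON")
  }
  x <- config
  x$generator <- gen[c("n_households", "max_plots_per_household", "n_plots",
                       "n_ea", "m5_n", "m6_n", "decay_mean", "decay_sd",
                       "error_sd", "error_tilt")]
  x$generator$spearman_targets <- unclass(gen$spearman_targets)
  x$generator$scheme <- unclass(gen$scheme)
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- x$generator
  st <- default_spearman_targets()
  if (!is.null(g$spearman_targets)) {
    st[, ] <- as.matrix(g$spearman_targets)
  }
  gen <- generator_config(
    n_households = g$n_households,
    max_plots_per_household = g$max_plots_per_household,
    n_plots = g$n_plots, n_ea = g$n_ea,
    spearman_targets = st,
    scheme = visual_aid_scheme(g$scheme$cuts, g$scheme$values),
    m5_n = g$m5_n, m6_n = g$m6_n,
    decay_mean = g$decay_mean, decay_sd = g$decay_sd,
    error_sd = g$error_sd, error_tilt = g$error_tilt)
  run_config(seed = x$seed, generator = gen,
             scene_width = x$scene_width, scene_height = x$scene_height,
             pixel_size_cm = x$pixel_size_cm, contrast = x$contrast,
             raster_noise_sd = x$raster_noise_sd, raster_k = x$raster_k,
             ndti_mode = x$ndti_mode, write_images = x$write_images)
}

#' Run the full residue-cover measurement experiment
#'
#' Orchestrates the pipeline end to end under a single seed: simulate the
#' survey; generate one ground-truth field scene per plot at the
#' benchmark cover and re-measure it with the simulated line transect and
#' the segmentation chain (pipeline `m5`); render the SWIR raster over
#' the plot coordinates and extract the scaled tillage index (pipeline
#' `m6`); then produce the comparison outputs (correlation matrix,
#' distribution summaries, threshold confusion, category tables, error
#' regressions). CSV outputs and the resolved configuration are written
#' under `out_dir`; a run with the same configuration and seed reproduces
#' them byte for byte.
#'
#' The pipeline-derived `m5`/`m6` replace the survey's copula-drawn
#' columns on the same observed subsets, so downstream analyses see the
#' instrument chain, not the dependence targets.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list of class `"run_report"` with the survey, the
#'   enriched plot table, analysis objects, per-stage row counts and the
#'   output paths.
#' @export
run_all <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  log <- list(seed = config$seed)

  ## stage 1: survey
  svy <- simulate_survey(config$generator, seed = config$seed)
  plots <- svy$plots
  np <- nrow(plots)
  log$plots <- np

  ## stage 2: imagery + transect + segmentation (only where m5 observed)
  seed_base <- config$seed %% 1000000L
  m5_rows <- which(!is.na(plots$m5))
  lt_transect <- rep(NA_real_, np)
  m5_pipe <- rep(NA_real_, np)
  n_clipped <- 0L
  for (i in m5_rows) {
    sc <- generate_field_scene(plots$lt[i], soil = plots$soil[i],
                               width = config$scene_width,
                               height = config$scene_height,
                               pixel_size_cm = config$pixel_size_cm,
                               contrast = config$contrast,
                               seed = seed_base + i)
    if (config$write_images) {
      img_dir <- file.path(out_dir, "images")
      dir.create(img_dir, showWarnings = FALSE)
      write_field_scene(sc,
                        file.path(img_dir, paste0(plots$plot_id[i], ".png")),
                        file.path(img_dir, paste0(plots$plot_id[i], "_mask.png")))
    }
    est <- withCallingHandlers(
      lt_estimate(sc, seed = seed_base + i),
      warning = function(w) {
        n_clipped <<- n_clipped + 1L
        invokeRestart("muffleWarning")
      })
    lt_transect[i] <- as.numeric(est)
    m5_pipe[i] <- segment_cover(sc$image)
  }
  plots$lt_transect <- lt_transect
  plots$m5 <- m5_pipe
  log$scenes <- length(m5_rows)
  log$transects_clipped <- n_clipped

  ## stage 3: raster + extraction (only where m6 observed)
  m6_rows <- which(!is.na(plots$m6))
  coords <- data.frame(x = stats::runif(np, 0, 3000),
                       y = stats::runif(np, 0, 3000))
  plots$x <- coords$x; plots$y <- coords$y
  raster_in <- data.frame(x = plots$x[m6_rows], y = plots$y[m6_rows],
                          cover = plots$lt[m6_rows],
                          soil = plots$soil[m6_rows])
  scene <- render_spectral_scene(raster_in, noise_sd = config$raster_noise_sd,
                                 k = config$raster_k,
                                 seed = seed_base + 777L)
  if (config$write_images) {
    write_spectral_scene(scene, file.path(out_dir, "swir.tif"))
  }
  ndti <- scale_ndti(compute_ndti(scene))
  m6_pipe <- rep(NA_real_, np)
  m6_pipe[m6_rows] <- extract_plot_value(ndti, scene$geotransform,
                                         raster_in, mode = config$ndti_mode)
  plots$m6 <- m6_pipe
  log$raster_px <- length(scene$swir1)

  ## stage 4: comparison
  cormat <- spearman_matrix(plots)
  summaries <- summarize_distributions(plots)
  confusion <- lapply(paste0("m", 1:6), function(m) confusion_30(plots, m))
  categories <- lapply(paste0("m", 1:6), function(m)
    category_false_reporting(plots, m))
  lpms <- lapply(paste0("m", 1:6), function(m)
    tryCatch(fit_lpm(plots, svy$households, m), error = function(e) {
      warning(sprintf("error regression for %s skipped: %s", m,
                      conditionMessage(e)), call. = FALSE)
      NULL
    }))
  names(confusion) <- names(categories) <- names(lpms) <- paste0("m", 1:6)
  lpms <- Filter(Negate(is.null), lpms)

  ## outputs
  utils::write.csv(plots, file.path(out_dir, "plots.csv"), row.names = FALSE)
  utils::write.csv(svy$households, file.path(out_dir, "households.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(method = rownames(cormat$rho),
                              round(cormat$rho, 4)),
                   file.path(out_dir, "table3.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(confusion, function(cf)
    data.frame(method = cf$method, t(cf$counts), n = cf$n,
               accuracy = cf$accuracy))),
    file.path(out_dir, "fig5.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, lapply(categories, function(ct)
    cbind(method = ct$method, ct$rates))),
    file.path(out_dir, "fig6.csv"), row.names = FALSE)
  lpm_tab <- do.call(rbind, lapply(lpms, function(f)
    data.frame(method = f$method, term = rownames(f$coefficients),
               estimate = f$coefficients[, 1], p = f$coefficients[, 4],
               stars = f$stars, n = f$n, adj_r2 = f$adj_r_squared,
               row.names = NULL)))
  if (is.null(lpm_tab)) {
    lpm_tab <- data.frame(method = character(), term = character(),
                          estimate = numeric(), p = numeric(),
                          stars = character(), n = integer(),
                          adj_r2 = numeric())
  }
  utils::write.csv(lpm_tab, file.path(out_dir, "table4.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(out_dir, "summaries.csv"),
                   row.names = FALSE)
  write_run_config(config, file.path(out_dir, "config.json"))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(structure(list(survey = svy, plots = plots, cormat = cormat,
                           summaries = summaries, confusion = confusion,
                           categories = categories, lpms = lpms, log = log,
                           out_dir = out_dir),
                      class = "run_report"))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("Pipeline run (seed %d): %d plots, %d scenes segmented, %d raster px\n",
              x$log$seed, x$log$plots, x$log$scenes, x$log$raster_px))
  cat(sprintf("outputs in %s\n", x$out_dir))
  invisible(x)
}
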