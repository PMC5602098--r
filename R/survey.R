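#' Configuration of the synthetic survey generator
#'
#' Collects every tunable of [simulate_survey()]. The defaults reproduce
#' the study design: 197 households across five enumeration areas, at
#' most two plots each for a total of 314 plots; drone-derived estimates
#' available for 182 plots and satellite-derived estimates for 251; and
#' the dependence and marginal structure of the seven measurement
#' methods.
#'
#' @param n_households Number of households.
#' @param max_plots_per_household Maximum plots sampled per household.
#' @param n_plots Total number of plots; must not exceed
#'   `n_households * max_plots_per_household`.
#' @param n_ea Number of enumeration areas households are spread over.
#' @param spearman_targets 7x7 Spearman target matrix, see
#'   [default_spearman_targets()].
#' @param marginals Named list of marginal quantile functions, see
#'   [default_marginals()].
#' @param scheme Visual-aid scheme used for `m3`/`m4`.
#' @param m5_n,m6_n Number of plots with non-missing `m5` / `m6`
#'   (missing-completely-at-random subsets of the plots).
#' @param decay_mean,decay_sd Mean and standard deviation of the
#'   proportional between-visit reduction used by [apply_decay()].
#' @param error_sd Baseline standard deviation (percent points) of the
#'   perception error added to the survey methods `m1`-`m4`.
#' @param error_tilt Scale (percent points per unit covariate index) of
#'   the systematic component of the perception error; see the package
#'   vignette for the error model.
#' @param seed Integer seed; all randomness of a run flows from it.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_households = 197L,
                             max_plots_per_household = 2L,
                             n_plots = 314L,
                             n_ea = 5L,
                             spearman_targets = default_spearman_targets(),
                             marginals = default_marginals(),
                             scheme = visual_aid_scheme(),
                             m5_n = 182L, m6_n = 251L,
                             decay_mean = 0.25, decay_sd = 0.12,
                             error_sd = 6, error_tilt = 5,
                             seed = NULL) {
  if (n_plots > n_households * max_plots_per_household) {
    stop("inconsistent config: n_plots exceeds n_households * max_plots_per_household")
  }
  stopifnot(m5_n <= n_plots, m6_n <= n_plots,
            decay_mean > 0 || decay_mean == 0, decay_mean < 1,
            decay_sd >= 0)
  R <- spearman_targets
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8)) {
    stop("spearman_targets must be symmetric with unit diagonal")
  }
  structure(list(n_households = as.integer(n_households),
                 max_plots_per_household = as.integer(max_plots_per_household),
                 n_plots = as.integer(n_plots),
                 n_ea = as.integer(n_ea),
                 spearman_targets = R,
                 marginals = marginals,
                 scheme = scheme,
                 m5_n = as.integer(m5_n), m6_n = as.integer(m6_n),
                 decay_mean = decay_mean, decay_sd = decay_sd,
                 error_sd = error_sd, error_tilt = error_tilt,
                 seed = seed),
            class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic residue-cover survey configuration\n")
  cat(sprintf("  households: %d (max %d plots each), plots: %d, EAs: %d\n",
              x$n_households, x$max_plots_per_household, x$n_plots, x$n_ea))
  cat(sprintf("  m5 observed: %d, m6 observed: %d\n", x$m5_n, x$m6_n))
  cat(sprintf("  decay: mean %.2f sd %.2f; error sd %.1f tilt %.1f\n",
              x$decay_mean, x$decay_sd, x$error_sd, x$error_tilt))
  invisible(x)
}

# Latent copula correlation matrix for the full seven-method draw: the
# closed-form link everywhere, with bisection-calibrated overrides for the
# two benchmark/visual-aid entries (the pairs whose post-discretization
# rank correlation the experiment compares against its targets).
survey_latent_correlation <- function(config) {
  R <- spearman_to_pearson(config$spearman_targets)
  diag(R) <- 1
  R["lt", "m3"] <- R["m3", "lt"] <- as.numeric(calibrate_discretized_rho(
    config$spearman_targets["lt", "m3"],
    config$marginals$lt, config$marginals$m3, scheme = config$scheme))
  R["lt", "m4"] <- R["m4", "lt"] <- as.numeric(calibrate_discretized_rho(
    config$spearman_targets["lt", "m4"],
    config$marginals$lt, config$marginals$m4, scheme = config$scheme))
  nearest_pd_correlation(R)
}

# Covariate index driving the perception-error layer: positive for large
# and distant fields, negative for sloped fields (better viewing angle).
# Centred so the index has approximately zero mean under the default
# covariate distributions.
perception_error_index <- function(field_size, distance, slope,
                                   p_slope = c(flat = 0.5, slight = 0.35,
                                               steep = 0.15)) {
  z_fs <- (log(field_size) - (log(2139) - 0.9^2 / 2)) / 0.9
  z_d <- pmin((distance - 433) / 600, 3)
  idx <- 0.45 * z_fs + 0.30 * z_d -
    0.45 * (slope == "slight") - 0.90 * (slope == "steep")
  centre <- -0.45 * p_slope[["slight"]] - 0.90 * p_slope[["steep"]]
  idx - centre
}

#' Simulate the residue-cover survey experiment
#'
#' Generates household and plot records whose seven cover measurements
#' follow a Gaussian copula with the configured rank-dependence targets
#' and marginals. The visual-aid methods (`m3`, `m4`) are reported both
#' as a six-level category and as the mapped percent value. The survey
#' methods `m1`-`m4` additionally carry a covariate-driven perception
#' error whose scale and direction follow field size, distance and slope
#' (see the vignette); the benchmark `lt` and the instrument-derived
#' `m5`/`m6` do not. `m5` and `m6` are missing completely at random so
#' that exactly `m5_n` and `m6_n` plots observe them.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A list of class `"residue_survey"` with data.frames `plots`
#'   and `households`.
#' @examples
#' svy <- simulate_survey(generator_config(seed = 1))
#' nrow(svy$plots); nrow(svy$households)
#' @export
simulate_survey <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  seed <- if (!is.null(seed)) seed else config$seed
  if (!is.null(seed)) set.seed(seed)
  nh <- config$n_households
  np <- config$n_plots

  ## households
  ea <- rep_len(seq_len(config$n_ea), nh)
  households <- data.frame(
    household_id = sprintf("hh%03d", seq_len(nh)),
    ea_id = sort(ea),
    head_sex = sample(c("male", "female"), nh, TRUE, c(0.494, 0.506)),
    head_age = pmax(18, round(stats::rnorm(nh, 46.2, 15))),
    head_education = stats::rpois(nh, 3.3),
    training = stats::runif(nh) < 0.5,
    farm_size = stats::rlnorm(nh, log(1.2) - 0.6^2 / 2, 0.6),
    herd_tlu = stats::rlnorm(nh, log(2.8) - 0.7^2 / 2, 0.7),
    phones = stats::rpois(nh, 1.3),
    stringsAsFactors = FALSE)

  ## household-to-plot assignment: the first households contribute the
  ## maximum number of plots, the remainder one, so totals are exact.
  extra <- np - nh
  stopifnot(extra >= 0)
  n_multi <- ceiling(extra / (config$max_plots_per_household - 1L))
  plots_per_hh <- rep(1L, nh)
  if (n_multi > 0) {
    plots_per_hh[seq_len(n_multi)] <- config$max_plots_per_household
    plots_per_hh[n_multi] <- config$max_plots_per_household -
      (n_multi * (config$max_plots_per_household - 1L) - extra)
  }
  hh_of_plot <- rep(seq_len(nh), plots_per_hh)

  ## plot covariates
  slope_lv <- c("flat", "slight", "steep")
  soil_lv <- c("cambisol", "leptosol", "luvisol", "vertisol")
  residue_lv <- c("barley", "maize", "teff", "wheat")
  field_size <- stats::rlnorm(np, log(2139) - 0.9^2 / 2, 0.9)
  distance <- stats::rlnorm(np, log(433) - 0.5, 1.0)
  slope <- sample(slope_lv, np, TRUE, c(0.50, 0.35, 0.15))
  soil <- sample(soil_lv, np, TRUE, c(0.146, 0.255, 0.207, 0.392))
  residue_type <- sample(residue_lv, np, TRUE, c(0.220, 0.280, 0.191, 0.309))
  rocks_gt20 <- stats::runif(np) < 0.2

  ## joint measurement draw through the latent Gaussian copula
  Rl <- survey_latent_correlation(config)
  L <- chol(Rl)
  z <- matrix(stats::rnorm(np * 7L), np, 7L) %*% L
  u <- stats::pnorm(z)
  colnames(u) <- method_names()
  mg <- config$marginals
  lt <- mg$lt(u[, "lt"])
  m1 <- mg$m1(u[, "m1"])
  m2 <- mg$m2(u[, "m2"])
  m3_u <- mg$m3(u[, "m3"])
  m4_u <- mg$m4(u[, "m4"])
  m5 <- mg$m5(u[, "m5"])
  m6 <- mg$m6(u[, "m6"])

  ## perception-error layer on the survey methods
  idx <- perception_error_index(field_size, distance, slope)
  sds <- config$error_sd * exp(0.3 * idx)
  tilt <- config$error_tilt * idx
  perturb <- function(v, share) {
    pmin(100, pmax(0, v - share * tilt + stats::rnorm(np, 0, share * sds)))
  }
  m1 <- perturb(m1, 1.0)
  m2 <- perturb(m2, 0.5)
  m3_u <- perturb(m3_u, 0.8)
  m4_u <- perturb(m4_u, 0.4)
  m3_cat <- discretize_cover(m3_u, config$scheme, "category")
  m4_cat <- discretize_cover(m4_u, config$scheme, "category")
  m3 <- config$scheme$values[m3_cat]
  m4 <- config$scheme$values[m4_cat]

  ## missing-completely-at-random instrument coverage
  m5[sample.int(np, np - config$m5_n)] <- NA_real_
  m6[sample.int(np, np - config$m6_n)] <- NA_real_

  plots <- data.frame(
    plot_id = sprintf("pl%03d", seq_len(np)),
    household_id = households$household_id[hh_of_plot],
    ea_id = households$ea_id[hh_of_plot],
    lt = lt, m1 = m1, m2 = m2,
    m3 = m3, m3_cat = m3_cat,
    m4 = m4, m4_cat = m4_cat,
    m5 = m5, m6 = m6,
    field_size = field_size, distance = distance,
    slope = slope, soil = soil, residue_type = residue_type,
    rocks_gt20 = rocks_gt20,
    stringsAsFactors = FALSE)

  structure(list(plots = plots, households = households, config = config),
            class = "residue_survey")
}

#' @export
print.residue_survey <- function(x, ...) {
  cat(sprintf("Synthetic residue-cover survey: %d plots, %d households\n",
              nrow(x$plots), nrow(x$households)))
  cat(sprintf("  m5 observed %d, m6 observed %d; median lt %.1f%%\n",
              sum(!is.na(x$plots$m5)), sum(!is.na(x$plots$m6)),
              stats::median(x$plots$lt)))
  invisible(x)
}

#' Apply between-visit residue decay to benchmark cover values
#'
#' Residue cover declines between visits (grazing, decomposition,
#' collection for fuel and feed). Each field receives an independent
#' proportional reduction drawn from a Beta distribution with the given
#' mean and standard deviation, so every second-visit value is at most
#' the first-visit value and the mean proportional reduction converges to
#' `decay_mean`.
#'
#' @param lt_values First-visit percent cover values in \[0, 100\].
#' @param decay_mean Mean proportional reduction, in \[0, 1).
#' @param decay_sd Standard deviation of the reduction; `0` gives the
#'   deterministic limit. Must satisfy
#'   `decay_sd^2 < decay_mean * (1 - decay_mean)` for a valid Beta law.
#' @param seed Optional integer seed.
#' @return Second-visit values, elementwise `<=` the input.
#' @examples
#' apply_decay(80, 0.25, 0)  # deterministic: 60
#' @export
apply_decay <- function(lt_values, decay_mean = 0.25, decay_sd = 0.12,
                        seed = NULL) {
  stopifnot(decay_mean >= 0, decay_mean < 1, decay_sd >= 0,
            all(lt_values >= 0 & lt_values <= 100))
  if (!is.null(seed)) set.seed(seed)
  n <- length(lt_values)
  if (decay_sd == 0 || decay_mean == 0) {
    d <- rep(decay_mean, n)
  } else {
    v <- decay_sd^2
    if (v >= decay_mean * (1 - decay_mean)) {
      stop("decay_sd too large for a Beta reduction with this mean")
    }
    conc <- decay_mean * (1 - decay_mean) / v - 1
    d <- stats::rbeta(n, decay_mean * conc, (1 - decay_mean) * conc)
  }
  lt_values * (1 - d)
}

#' Write survey tables to CSV
#'
#' @param survey A `"residue_survey"` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`plots.csv`, `households.csv`).
#' @export
write_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "residue_survey"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(plots = file.path(dir, "plots.csv"),
             households = file.path(dir, "households.csv"))
  utils::write.csv(survey$plots, paths["plots"], row.names = FALSE)
  utils::write.csv(survey$households, paths["households"], row.names = FALSE)
  invisible(paths)
}
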