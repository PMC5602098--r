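#' Convert a Spearman rank correlation to a Gaussian copula parameter
#'
#' For a bivariate Gaussian copula with linear correlation \eqn{\rho}, the
#' Spearman rank correlation of any pair with continuous marginals is
#' \eqn{\rho_s = (6/\pi)\,\mathrm{asin}(\rho/2)}. This function inverts that
#' relation, returning the copula parameter \eqn{\rho = 2\sin(\pi\rho_s/6)}
#' that reproduces a target rank correlation. The map is exact only for
#' continuous marginals; discretized marginals need
#' [calibrate_discretized_rho()].
#'
#' @param rho_s Target Spearman rank correlation, in \[-1, 1\]. Vectorised.
#' @return Copula (Pearson, latent-normal) parameter in \[-1, 1\], monotone
#'   increasing in `rho_s`.
#' @examples
#' spearman_to_pearson(c(0, 0.76, 1))
#' @export
spearman_to_pearson <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) > 1)) {
    stop("rho_s must be finite and within [-1, 1]")
  }
  2 * sin(pi * rho_s / 6)
}

#' Spearman rank correlation implied by a Gaussian copula parameter
#'
#' Inverse companion of [spearman_to_pearson()]; exact for continuous
#' marginals.
#'
#' @param rho Copula parameter in \[-1, 1\].
#' @return Spearman rank correlation.
#' @export
pearson_to_spearman <- function(rho) {
  if (any(!is.finite(rho)) || any(abs(rho) > 1)) {
    stop("rho must be finite and within [-1, 1]")
  }
  (6 / pi) * asin(rho / 2)
}

#' Six-level visual-aid classification scheme
#'
#' The visual-aid survey instrument asks the respondent to pick one of six
#' reference photographs of increasing residue cover. This scheme maps a
#' percent cover to the category index and to the representative percent
#' value attached to each photo. Cut points bracket the conventional 30%
#' adoption threshold.
#'
#' @param cuts Increasing interior cut points on the percent scale
#'   (length 5 for six categories).
#' @param values Representative percent value reported for each category
#'   (length 6).
#' @return A list with elements `cuts` and `values`, class
#'   `"visual_aid_scheme"`.
#' @export
visual_aid_scheme <- function(cuts = c(10, 25, 40, 60, 80),
                              values = c(5, 17.5, 32.5, 50, 70, 90)) {
  stopifnot(length(values) == length(cuts) + 1L,
            !is.unsorted(cuts, strictly = TRUE),
            !is.unsorted(values, strictly = TRUE))
  structure(list(cuts = cuts, values = values), class = "visual_aid_scheme")
}

#' Discretize percent cover through a visual-aid scheme
#'
#' @param cover Percent cover values in \[0, 100\].
#' @param scheme A [visual_aid_scheme()].
#' @param what `"value"` for the mapped percent, `"category"` for the
#'   1-based category index.
#' @return Numeric (mapped percent) or integer (category index) vector.
#' @export
discretize_cover <- function(cover, scheme = visual_aid_scheme(),
                             what = c("value", "category")) {
  what <- match.arg(what)
  if (any(cover < 0 | cover > 100, na.rm = TRUE)) {
    stop("cover must lie in [0, 100]")
  }
  cat_idx <- findInterval(cover, scheme$cuts) + 1L
  if (what == "category") cat_idx else scheme$values[cat_idx]
}

#' Calibrate a Gaussian copula parameter for a discretized margin
#'
#' When one margin is reported through a six-level visual-aid scheme, the
#' closed-form link between the copula parameter and Spearman's rho no
#' longer holds: discretization compresses rank variation and the
#' post-discretization rank correlation falls below the continuous one.
#' This routine finds, by bisection against a common-random-numbers Monte
#' Carlo evaluation (so the objective is exactly monotone in the
#' parameter), the copula parameter whose post-discretization sample
#' Spearman matches the target.
#'
#' @param rho_s_target Target Spearman rank correlation after
#'   discretization of margin b.
#' @param marginal_a,marginal_b Quantile functions for the two margins on
#'   the percent scale (margin b is discretized after transformation).
#' @param scheme [visual_aid_scheme()] applied to margin b.
#' @param n Monte Carlo sample size per bisection evaluation.
#' @param tol Bisection tolerance on the achieved Spearman.
#' @param seed Integer seed for the common random numbers.
#' @return The calibrated copula parameter, with attribute `achieved`
#'   giving the Monte Carlo Spearman at the returned parameter. Errors if
#'   the target exceeds the maximum attainable post-discretization
#'   Spearman (reported in the error message).
#' @export
calibrate_discretized_rho <- function(rho_s_target,
                                      marginal_a = lt_quantile,
                                      marginal_b = lt_quantile,
                                      scheme = visual_aid_scheme(),
                                      n = 200000L, tol = 0.003,
                                      seed = 20151207L) {
  stopifnot(abs(rho_s_target) <= 1, n >= 1000)
  if (rho_s_target == 0) {
    return(structure(0, achieved = 0))
  }
  key <- paste(rho_s_target, n, seed,
               paste(scheme$cuts, collapse = ","),
               paste(scheme$values, collapse = ","),
               paste(deparse(body(marginal_a)), collapse = ""),
               paste(deparse(body(marginal_b)), collapse = ""),
               sep = "|")
  hit <- .calibration_cache[[key]]
  if (!is.null(hit)) return(hit)
  sgn <- sign(rho_s_target)
  target <- abs(rho_s_target)
  # common random numbers under a private stream; the caller's RNG state
  # is left untouched so seeded simulations stay reproducible
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(2L * n), ncol = 2L)
  eval_rho <- function(rho) {
    zb <- rho * z[, 1L] + sqrt(1 - rho^2) * z[, 2L]
    a <- marginal_a(stats::pnorm(z[, 1L]))
    b <- discretize_cover(marginal_b(stats::pnorm(zb)), scheme)
    stats::cor(a, b, method = "spearman")
  }
  max_att <- eval_rho(0.999999)
  if (target > max_att + tol) {
    stop(sprintf(paste0("target Spearman %.3f is unattainable under this ",
                        "discretization (maximum attainable ~ %.3f)"),
                 target, max_att))
  }
  lo <- 0; hi <- 0.999999
  for (i in seq_len(40L)) {
    mid <- (lo + hi) / 2
    if (eval_rho(mid) < target) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  out <- (lo + hi) / 2
  ach <- eval_rho(out)
  if (abs(ach - target) > max(tol, 0.01)) {
    stop(sprintf("bisection failed to reach target %.3f (achieved %.3f)",
                 target, ach))
  }
  res <- structure(sgn * out, achieved = sgn * ach)
  .calibration_cache[[key]] <- res
  res
}

# session cache of bisection calibrations (keyed by target, Monte Carlo
# settings, scheme and marginals)
.calibration_cache <- new.env(parent = emptyenv())

#' Sample pairs from a bivariate Gaussian copula with given marginals
#'
#' Draws `n` latent bivariate normal pairs with correlation chosen so the
#' sample Spearman rank correlation converges to `rho_s_target`, then maps
#' each margin through its quantile function. If `discretize_b` is given,
#' margin b is additionally reported through the six-level visual-aid
#' scheme and the copula parameter is first calibrated with
#' [calibrate_discretized_rho()] so the *post-discretization* Spearman
#' matches the target.
#'
#' @param rho_s_target Target Spearman rank correlation in \[-1, 1\].
#' @param marginal_a,marginal_b Quantile functions on the percent scale.
#' @param n Number of pairs (at least 2).
#' @param seed Integer seed.
#' @param discretize_b Optional [visual_aid_scheme()] applied to margin b.
#' @param rho Optional pre-computed copula parameter overriding the
#'   link/calibration (used to avoid re-calibrating in repeated draws).
#' @return A data.frame with columns `a` and `b`.
#' @examples
#' p <- sample_copula_pair(0.73, n = 5000, seed = 1)
#' cor(p$a, p$b, method = "spearman")
#' @export
sample_copula_pair <- function(rho_s_target,
                               marginal_a = lt_quantile,
                               marginal_b = lt_quantile,
                               n, seed = NULL,
                               discretize_b = NULL, rho = NULL) {
  stopifnot(abs(rho_s_target) <= 1, n >= 2)
  check_degenerate <- function(q, nm) {
    v <- q(c(0.05, 0.5, 0.95))
    if (length(unique(v)) == 1L) {
      stop(sprintf("marginal '%s' is degenerate (constant): %s",
                   nm, "rank correlation is undefined"))
    }
  }
  check_degenerate(marginal_a, "a")
  check_degenerate(marginal_b, "b")
  if (is.null(rho)) {
    rho <- if (is.null(discretize_b)) {
      spearman_to_pearson(rho_s_target)
    } else {
      as.numeric(calibrate_discretized_rho(
        rho_s_target, marginal_a, marginal_b, scheme = discretize_b))
    }
  }
  if (!is.null(seed)) set.seed(seed)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  a <- marginal_a(stats::pnorm(z1))
  b <- marginal_b(stats::pnorm(z2))
  if (!is.null(discretize_b)) b <- discretize_cover(b, discretize_b)
  data.frame(a = a, b = b)
}

#' Repair a correlation matrix to the nearest positive-definite one
#'
#' Pairwise-assembled correlation matrices need not be positive definite;
#' this applies the Higham nearest-PD projection (via [Matrix::nearPD()])
#' constrained to unit diagonal. The default seven-method matrix is
#' already positive definite, so the repair is then an identity.
#'
#' @param R Symmetric matrix with unit diagonal.
#' @return Positive semi-definite correlation matrix of the same dimension.
#' @export
nearest_pd_correlation <- function(R) {
  stopifnot(is.matrix(R), nrow(R) == ncol(R))
  if (max(abs(R - t(R))) > 1e-8 || any(abs(diag(R) - 1) > 1e-8)) {
    stop("R must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= 1e-10) return(R)
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE)$mat)
  dimnames(out) <- dimnames(R)
  out
}

#' Reference rank-correlation structure of the seven measurement methods
#'
#' The default dependence targets of the survey generator: Spearman rank
#' correlations between the line-transect benchmark and the six
#' alternative methods (and among the alternatives), as used throughout
#' the method-comparison experiment. The LT-M5 entry is negative: in the
#' field experiment the drone segmentation failed under uncontrolled
#' lighting, and the generator reproduces that rank structure rather than
#' the segmenter's intrinsic accuracy.
#'
#' @return A 7x7 symmetric matrix with dimnames
#'   `c("lt","m1","m2","m3","m4","m5","m6")`.
#' @export
default_spearman_targets <- function() {
  m <- matrix(c(
     1.00, 0.60, 0.73, 0.59, 0.76, -0.25, 0.57,
     0.60, 1.00, 0.68, 0.76, 0.62, -0.32, 0.42,
     0.73, 0.68, 1.00, 0.55, 0.75, -0.16, 0.39,
     0.59, 0.76, 0.55, 1.00, 0.60, -0.26, 0.42,
     0.76, 0.62, 0.75, 0.60, 1.00, -0.28, 0.47,
    -0.25,-0.32,-0.16,-0.26,-0.28,  1.00, 0.09,
     0.57, 0.42, 0.39, 0.42, 0.47,  0.09, 1.00), 7, 7)
  dimnames(m) <- list(method_names(), method_names())
  m
}

method_names <- function() c("lt", "m1", "m2", "m3", "m4", "m5", "m6")
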