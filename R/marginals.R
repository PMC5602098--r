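#' @name marginals
#' @title Default marginal distributions of the measurement methods
#'
#' @description
#' Quantile functions on the percent-cover scale used by the survey
#' generator. The line-transect (benchmark) marginal is a Beta
#' distribution rescaled to \[0, 100\] whose two shape parameters were
#' solved (once, numerically) so that the median is 60 and the
#' probability of exceeding 90 is 0.04. The alternative-method marginals
#' are rescaled versions fixed by their median offsets from the
#' benchmark:
#'
#' * `m1` (interviewee estimate): median 30, i.e. the benchmark scaled by
#'   30/60;
#' * `m2` (enumerator estimate): median 32.5 (scale 32.5/60);
#' * `m5` (drone segmentation): median 55 and a visibly tighter spread
#'   (Beta with total concentration 25), reflecting the compressed range
#'   of image-derived estimates;
#' * `m6` (satellite tillage index): identical to the benchmark marginal.
#'
#' The visual-aid methods (`m3`, `m4`) have no continuous marginal of
#' their own: they discretize an underlying percent perception (`m1`-like
#' for the interviewee, benchmark-like for the enumerator) through
#' [visual_aid_scheme()].
#'
#' @param u Probabilities in \[0, 1\].
#' @return Percent cover quantiles in \[0, 100\].
NULL

# Beta shape parameters of the benchmark marginal (median 60, P(>90)=0.04).
LT_BETA_SHAPE1 <- 3.1338706
LT_BETA_SHAPE2 <- 2.1938685

# Concentration (shape1 + shape2) of the drone-method marginal.
M5_BETA_CONC <- 25

#' @rdname marginals
#' @export
lt_quantile <- function(u) 100 * stats::qbeta(u, LT_BETA_SHAPE1, LT_BETA_SHAPE2)

#' @rdname marginals
#' @export
m1_quantile <- function(u) (30 / 60) * lt_quantile(u)

#' @rdname marginals
#' @export
m2_quantile <- function(u) (32.5 / 60) * lt_quantile(u)

#' @rdname marginals
#' @export
m5_quantile <- function(u) {
  a <- m5_beta_shape1()
  100 * stats::qbeta(u, a, M5_BETA_CONC - a)
}

#' @rdname marginals
#' @export
m6_quantile <- function(u) lt_quantile(u)

# Shape1 of the m5 Beta: median 0.55 at fixed concentration, solved once
# and cached for the session.
m5_beta_shape1 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      f <- function(a) stats::qbeta(0.5, a, M5_BETA_CONC - a) - 0.55
      cache <<- stats::uniroot(f, c(1, M5_BETA_CONC - 1), tol = 1e-10)$root
    }
    cache
  }
})

#' Default marginal quantile functions keyed by method id
#'
#' @return Named list of quantile functions for the continuous methods
#'   (`lt`, `m1`, `m2`, `m5`, `m6`) and of the underlying perceptions of
#'   the visual-aid methods (`m3`, `m4`).
#' @export
default_marginals <- function() {
  list(lt = lt_quantile,
       m1 = m1_quantile,
       m2 = m2_quantile,
       m3 = m1_quantile,  # underlying interviewee perception
       m4 = lt_quantile,  # underlying enumerator perception
       m5 = m5_quantile,
       m6 = m6_quantile)
}
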