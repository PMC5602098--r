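#' Spearman correlation matrix across measurement methods
#'
#' Pairwise-complete Spearman rank correlations (average ranks for ties)
#' between the percent-scale measurements, with the number of complete
#' pairs and a two-sided significance test per cell. A cell whose pair
#' has an all-tied (constant) vector has no defined correlation and is
#' returned as `NA` with `significant = FALSE`.
#'
#' @param plots data.frame of plot records.
#' @param methods Column names to correlate; defaults to the seven
#'   measurement columns.
#' @param alpha Significance level for the flag matrix.
#' @return A list of class `"spearman_matrix"`: `rho` (symmetric,
#'   unit-diagonal matrix), `n` (pairwise complete counts), `p_value`,
#'   `significant`.
#' @export
spearman_matrix <- function(plots, methods = method_names(),
                            alpha = 0.001) {
  stopifnot(all(methods %in% names(plots)))
  x <- as.matrix(plots[methods])
  k <- length(methods)
  rho <- diag(1, k); nm <- matrix(NA_integer_, k, k); pv <- matrix(NA_real_, k, k)
  dimnames(rho) <- dimnames(nm) <- dimnames(pv) <- list(methods, methods)
  diag(nm) <- as.integer(colSums(!is.na(x)))
  diag(pv) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(x[, c(i, j)])
    nij <- sum(ok)
    nm[i, j] <- nm[j, i] <- nij
    if (nij < 3L) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    xi <- x[ok, i]; xj <- x[ok, j]
    if (length(unique(xi)) == 1L || length(unique(xj)) == 1L) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    ct <- suppressWarnings(stats::cor.test(xi, xj, method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    pv[i, j] <- pv[j, i] <- ct$p.value
  }
  structure(list(rho = rho, n = nm, p_value = pv,
                 significant = !is.na(pv) & pv < alpha, alpha = alpha),
            class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("Spearman rank correlations (pairwise complete)\n")
  m <- format(round(x$rho, digits))
  m[!x$significant & row(m) != col(m)] <- paste0(
    m[!x$significant & row(m) != col(m)], "*")
  print(m, quote = FALSE)
  cat(sprintf("* not significant at alpha = %g\n", x$alpha))
  invisible(x)
}

#' Five-number summaries and median gaps versus the benchmark
#'
#' @param plots data.frame of plot records.
#' @param methods Measurement columns to summarise.
#' @param benchmark Column used for the median-difference column.
#' @return data.frame with min, quartiles, max, n and
#'   `median_diff_vs_benchmark` per method; missing values are ignored.
#' @export
summarize_distributions <- function(plots, methods = method_names(),
                                    benchmark = "lt") {
  stopifnot(all(methods %in% names(plots)), benchmark %in% names(plots))
  med_bench <- stats::median(plots[[benchmark]], na.rm = TRUE)
  rows <- lapply(methods, function(m) {
    v <- plots[[m]]
    if (all(is.na(v))) stop(sprintf("method column '%s' is entirely missing", m))
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), na.rm = TRUE, names = FALSE)
    data.frame(method = m, min = q[1], q1 = q[2], median = q[3], q3 = q[4],
               max = q[5], n = sum(!is.na(v)),
               median_diff_vs_benchmark = q[3] - med_bench)
  })
  do.call(rbind, rows)
}

#' Classify adoption at a minimum-cover threshold
#'
#' Adoption requires *at least* the threshold cover, so the comparison is
#' inclusive.
#'
#' @param cover Percent cover in \[0, 100\] (NA allowed).
#' @param threshold Minimum cover defining adoption.
#' @return Logical vector.
#' @examples
#' classify_adoption(c(29.9, 30, 100))
#' @export
classify_adoption <- function(cover, threshold = 30) {
  if (any(cover < 0 | cover > 100, na.rm = TRUE)) {
    stop("cover must lie in [0, 100]")
  }
  cover >= threshold
}

#' Confusion of a method against the benchmark at the adoption threshold
#'
#' Cross-classifies plots by benchmark and method adoption status at the
#' threshold, over the plots where both are observed.
#'
#' @param plots data.frame of plot records.
#' @param method Method column name.
#' @param benchmark Benchmark column name.
#' @param threshold Adoption threshold, percent.
#' @return A list of class `"threshold_confusion"`: `method`, `counts`
#'   (named: correct_adopter, correct_nonadopter, false_positive,
#'   false_negative), `n`, `accuracy` (percent).
#' @export
confusion_30 <- function(plots, method, benchmark = "lt", threshold = 30) {
  stopifnot(method %in% names(plots), benchmark %in% names(plots))
  ok <- stats::complete.cases(plots[c(benchmark, method)])
  if (!any(ok)) stop("no plots observe both measures")
  b <- classify_adoption(plots[[benchmark]][ok], threshold)
  m <- classify_adoption(plots[[method]][ok], threshold)
  counts <- c(correct_adopter = sum(b & m),
              correct_nonadopter = sum(!b & !m),
              false_positive = sum(!b & m),
              false_negative = sum(b & !m))
  structure(list(method = method, counts = counts, n = sum(ok),
                 threshold = threshold,
                 accuracy = 100 * (counts[["correct_adopter"]] +
                                     counts[["correct_nonadopter"]]) / sum(ok)),
            class = "threshold_confusion")
}

#' @export
print.threshold_confusion <- function(x, ...) {
  cat(sprintf("Adoption confusion at %g%% threshold, %s vs benchmark (n = %d)\n",
              x$threshold, x$method, x$n))
  print(x$counts)
  cat(sprintf("accuracy: %.1f%%\n", x$accuracy))
  invisible(x)
}

#' AQUASTAT cover category of a percent cover
#'
#' The graded adoption classes: below 30, 30-60, 60-90 and above 90
#' percent ground cover. Bins are lower-inclusive (half-open), so 30
#' falls in "30-60" and 60 in "60-90"; 100 belongs to ">90".
#'
#' @param cover Percent cover in \[0, 100\] (NA allowed).
#' @return Factor with levels `<30`, `30-60`, `60-90`, `>90`.
#' @export
aquastat_category <- function(cover) {
  if (any(cover < 0 | cover > 100, na.rm = TRUE)) {
    stop("cover must lie in [0, 100]")
  }
  cut(cover, c(-Inf, 30, 60, 90, Inf), right = FALSE,
      labels = c("<30", "30-60", "60-90", ">90"))
}

#' Category-level false reporting of a method against the benchmark
#'
#' Cross-tabulates the benchmark AQUASTAT category against the method's,
#' and summarises per benchmark category the fraction of plots the method
#' places below, within, or above it.
#'
#' @inheritParams confusion_30
#' @return A list of class `"category_table"`: `table` (benchmark in
#'   rows), `rates` (data.frame with under/correct/over fractions per
#'   benchmark category), `n`.
#' @export
category_false_reporting <- function(plots, method, benchmark = "lt") {
  stopifnot(method %in% names(plots), benchmark %in% names(plots))
  ok <- stats::complete.cases(plots[c(benchmark, method)])
  b <- aquastat_category(plots[[benchmark]][ok])
  m <- aquastat_category(plots[[method]][ok])
  tab <- table(benchmark = b, method = m)
  bi <- as.integer(b); mi <- as.integer(m)
  rates <- do.call(rbind, lapply(seq_along(levels(b)), function(k) {
    in_cat <- bi == k
    data.frame(category = levels(b)[k], n = sum(in_cat),
               under = if (any(in_cat)) mean(mi[in_cat] < k) else NA_real_,
               correct = if (any(in_cat)) mean(mi[in_cat] == k) else NA_real_,
               over = if (any(in_cat)) mean(mi[in_cat] > k) else NA_real_)
  }))
  structure(list(method = method, table = tab, rates = rates, n = sum(ok)),
            class = "category_table")
}

#' @export
print.category_table <- function(x, ...) {
  cat(sprintf("AQUASTAT category cross-tabulation, %s vs benchmark (n = %d)\n",
              x$method, x$n))
  print(x$table)
  print(x$rates, row.names = FALSE)
  invisible(x)
}

#' Binary measurement-error outcome at the adoption threshold
#'
#' 1 when the method's adoption classification (false positive or false
#' negative) disagrees with the benchmark's at the threshold, 0 when they
#' agree, `NA` when the method is unobserved (rows later excluded from
#' the error regressions, which drives their smaller n).
#'
#' @inheritParams confusion_30
#' @return Integer vector of 0/1/NA, one per plot.
#' @export
measurement_error_outcome <- function(plots, method, benchmark = "lt",
                                      threshold = 30) {
  stopifnot(method %in% names(plots), benchmark %in% names(plots))
  b <- classify_adoption(plots[[benchmark]], threshold)
  m <- classify_adoption(plots[[method]], threshold)
  as.integer(b != m)
}

#' Linear probability model of a binary outcome on a design table
#'
#' Ordinary least squares of a 0/1 outcome on the supplied covariates
#' (plus an intercept; an empty design gives the intercept-only model).
#' Perfect separation is not an error for a linear probability model.
#'
#' @param outcome Numeric 0/1 vector.
#' @param covariates data.frame of covariates (may have zero columns),
#'   with `nrow(covariates) == length(outcome)`.
#' @return A list of class `"lpm_fit"`; see [fit_lpm()].
#' @examples
#' lpm(c(0, 1, 0, 1), data.frame(x = c(0, 1, 0, 1)))$coefficients
#' @export
lpm <- function(outcome, covariates = NULL) {
  stopifnot(all(outcome %in% c(0, 1)))
  if (is.null(covariates) || ncol(covariates) == 0L) {
    dat <- data.frame(error = outcome)
    form <- error ~ 1
  } else {
    stopifnot(nrow(covariates) == length(outcome))
    dat <- cbind(error = outcome, covariates)
    form <- stats::reformulate(names(covariates), response = "error")
  }
  fit <- stats::lm(form, data = dat)
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design after dummy coding")
  }
  if (fit$df.residual < 0) stop("more parameters than observations")
  sm <- summary(fit)
  co <- sm$coefficients
  stars <- ifelse(co[, 4] < 0.01, "***",
                  ifelse(co[, 4] < 0.05, "**",
                         ifelse(co[, 4] < 0.1, "*", "")))
  structure(list(coefficients = co, stars = stars,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 n = length(outcome), method = "custom",
                 reference_levels = NULL, fit = fit),
            class = "lpm_fit")
}

#' Linear probability model of measurement error
#'
#' Ordinary least squares of the binary error outcome on plot (and, for
#' the interviewee-reported methods, household) covariates, the standard
#' linear-probability specification: coefficients read directly as
#' probability effects, with plain OLS standard errors and t tests
#' starred at the 0.1 / 0.05 / 0.01 levels. Dummy coding uses the
#' reference levels male household head, teff residue, leptosol soil and
#' flat slope. Household covariates (head sex, age, education, training,
#' farm size, herd size, phones, distance) enter only for the
#' interviewee methods `m1` and `m3`; field covariates (field size,
#' residue type, soil type, rocks, slope) enter for every method. Rows
#' with a missing outcome are excluded.
#'
#' @param plots data.frame of plot records (needs `household_id` and the
#'   covariate columns of [simulate_survey()] output).
#' @param households Matching household data.frame (required for `m1`
#'   and `m3`).
#' @param method Method column the error outcome is computed for.
#' @param benchmark,threshold Passed to [measurement_error_outcome()].
#' @return A list of class `"lpm_fit"`: `coefficients` (matrix with
#'   estimate, se, t, p, stars), `adj_r_squared`, `r_squared`, `n`,
#'   `method`, `reference_levels`, and the underlying `lm` fit.
#' @export
fit_lpm <- function(plots, households = NULL, method,
                    benchmark = "lt", threshold = 30) {
  outcome <- measurement_error_outcome(plots, method, benchmark, threshold)
  dat <- plots
  dat$error <- outcome
  interviewee <- method %in% c("m1", "m3")
  if (interviewee) {
    if (is.null(households)) {
      stop("households table required for interviewee methods")
    }
    dat <- merge(dat, households, by = "household_id", sort = FALSE)
  }
  dat <- dat[!is.na(dat$error), , drop = FALSE]
  refs <- c(head_sex = "male", residue_type = "teff", soil = "leptosol",
            slope = "flat")
  # reference level first; unused levels dropped so small subsets stay
  # estimable
  ref_factor <- function(x, ref, all_levels) {
    lv <- intersect(c(ref, setdiff(all_levels, ref)), unique(x))
    factor(x, levels = lv)
  }
  dat$residue_type <- ref_factor(dat$residue_type, "teff",
                                 c("barley", "maize", "teff", "wheat"))
  dat$soil <- ref_factor(dat$soil, "leptosol",
                         c("cambisol", "leptosol", "luvisol", "vertisol"))
  dat$slope <- ref_factor(dat$slope, "flat", c("flat", "slight", "steep"))
  rhs <- c("field_size", "residue_type", "soil", "rocks_gt20", "slope")
  if (interviewee) {
    dat$head_sex <- ref_factor(dat$head_sex, "male", c("male", "female"))
    rhs <- c("head_sex", "head_age", "head_education", "training",
             "farm_size", "herd_tlu", "phones", "distance", rhs)
  }
  form <- stats::reformulate(rhs, response = "error")
  fit <- stats::lm(form, data = dat)
  if (fit$df.residual <= 0) stop("more parameters than observations")
  qr_rank <- fit$rank
  if (qr_rank < length(stats::coef(fit))) {
    stop("rank-deficient design after dummy coding")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  stars <- ifelse(co[, 4] < 0.01, "***",
                  ifelse(co[, 4] < 0.05, "**",
                         ifelse(co[, 4] < 0.1, "*", "")))
  structure(list(coefficients = co, stars = stars,
                 adj_r_squared = sm$adj.r.squared,
                 r_squared = sm$r.squared,
                 n = nrow(dat), method = method,
                 reference_levels = refs, fit = fit),
            class = "lpm_fit")
}

#' @export
print.lpm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Linear probability model of measurement error: %s (n = %d)\n",
              x$method, x$n))
  est <- cbind(format(round(x$coefficients[, 1], digits)), x$stars)
  colnames(est) <- c("estimate", "")
  print(est, quote = FALSE)
  cat(sprintf("adjusted R-squared: %.3f  (*, **, *** at 0.1, 0.05, 0.01)\n",
              x$adj_r_squared))
  invisible(x)
}
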