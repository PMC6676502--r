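#' Summarise per-image intensities by group
#'
#' Collapses an image-level table (one row per image, e.g. the run summary
#' from [run_batch()]) into per-group sample statistics. Standard deviations
#' use the n-1 denominator throughout (biological replicates).
#'
#' @param data Data frame with one row per image.
#' @param value Column of image-level values (default `mean_corrected_mean`).
#' @param group Grouping column (default `group`).
#' @return Tibble with `group`, `n`, `mean`, `sd`, `cv`.
#' @export
group_summaries <- function(data, value = mean_corrected_mean, group = group) {
  data |>
    dplyr::group_by(group = {{ group }}) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean({{ value }}),
      sd = sd({{ value }}),
      cv = sd / mean,
      .groups = "drop"
    )
}

#' Fold-change of experimental groups over a control group
#'
#' The fold-change is the ratio of the experimental group's mean image-level
#' intensity to the control group's mean. Its dispersion is the standard
#' deviation of the per-image folds (each experimental image divided by the
#' control mean), reported alongside.
#'
#' @inheritParams group_summaries
#' @param control Name of the control group (default `"control"`).
#' @return Tibble with one row per non-control group: `control_group`,
#'   `group`, `n_control`, `n`, `fold`, `sd`.
#' @examples
#' df <- data.frame(
#'   group = rep(c("control", "mutant"), each = 4),
#'   mean_corrected_mean = c(24, 26, 25, 25, 99, 101, 100, 100)
#' )
#' fold_change(df)
#' @export
fold_change <- function(data, value = mean_corrected_mean, group = group,
                        control = "control") {
  vals <- dplyr::pull(data, {{ value }})
  grps <- as.character(dplyr::pull(data, {{ group }}))
  if (!control %in% grps) {
    stop("input error: control group '", control, "' not present")
  }
  ctrl <- vals[grps == control]
  ctrl_mean <- mean(ctrl)
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("input error: control mean must be positive (got ",
         format(ctrl_mean), "); fold-change is undefined")
  }
  other <- setdiff(unique(grps), control)
  purrr::map_dfr(other, function(g) {
    v <- vals[grps == g]
    folds <- v / ctrl_mean
    tibble::tibble(control_group = control, group = g,
                   n_control = length(ctrl), n = length(v),
                   fold = mean(v) / ctrl_mean,
                   sd = if (length(v) > 1) sd(folds) else NA_real_)
  })
}

#' Per-image fold over the control mean
#'
#' Adds a `fold` column: each image-level value divided by the control
#' group's mean. Control images get their own fold (centred on 1), matching
#' the per-image panels used to compare analyses image by image.
#'
#' @inheritParams fold_change
#' @return `data` as a tibble with an added `fold` column.
#' @export
per_image_fold <- function(data, value = mean_corrected_mean, group = group,
                           control = "control") {
  vals <- dplyr::pull(data, {{ value }})
  grps <- as.character(dplyr::pull(data, {{ group }}))
  if (!control %in% grps) {
    stop("input error: control group '", control, "' not present")
  }
  ctrl_mean <- mean(vals[grps == control])
  if (!is.finite(ctrl_mean) || ctrl_mean <= 0) {
    stop("input error: control mean must be positive; fold is undefined")
  }
  dplyr::mutate(tibble::as_tibble(data), fold = {{ value }} / ctrl_mean)
}

#' Agreement between two paired sets of per-image readings
#'
#' Ordinary least-squares regression of `b` on `a` for paired per-image
#' values (e.g. the same images quantified by two methods or two users),
#' reporting the slope, intercept and R-squared. Perfect agreement is slope
#' 1, intercept 0, R-squared 1.
#'
#' @param data Data frame of paired readings.
#' @param a,b Columns with the paired values; `b` is regressed on `a`.
#' @return An object of class `fq_agreement`; use [tidy()] for the
#'   coefficient table, [glance()] for the fit summary, and [autoplot()]
#'   for a scatter plot with the fitted and identity lines.
#' @export
agreement <- function(data, a, b) {
  x <- dplyr::pull(data, {{ a }})
  y <- dplyr::pull(data, {{ b }})
  if (length(x) != length(y)) stop("input error: paired lists differ in length")
  if (length(x) < 3) stop("input error: need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("input error: constant input; agreement is undefined")
  }
  fit <- lm(y ~ x, data = data.frame(x = x, y = y))
  structure(
    list(model = fit, n = length(x),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = stats::cor(x, y)^2,
         data = tibble::tibble(a = x, b = y)),
    class = "fq_agreement"
  )
}

#' @export
print.fq_agreement <- function(x, ...) {
  cat(sprintf(
    "<fq_agreement> n = %d: b = %.4f * a + %.4f, R^2 = %.4f\n",
    x$n, x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' @export
tidy.fq_agreement <- function(x, ...) {
  # a perfect fit trips summary.lm's reliability warning; not useful here
  s <- suppressWarnings(summary(x$model))$coefficients
  tibble::tibble(
    term = c("(Intercept)", "a"),
    estimate = unname(s[, "Estimate"]),
    std.error = unname(s[, "Std. Error"]),
    statistic = unname(s[, "t value"]),
    p.value = unname(s[, "Pr(>|t|)"])
  )
}

#' @export
glance.fq_agreement <- function(x, ...) {
  s <- suppressWarnings(summary(x$model))
  tibble::tibble(
    r.squared = x$r_squared, slope = x$slope, intercept = x$intercept,
    sigma = s$sigma, n = x$n
  )
}

#' Coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) divided by the mean: the
#' dispersion measure used to compare staining variability between
#' processing schemes. Scale-invariant but not translation-invariant —
#' shifting the data changes the CV.
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @return The CV as a plain ratio.
#' @examples
#' coefficient_of_variation(c(8, 12))  # 0.2828...
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("input error: need at least 2 values")
  m <- mean(values)
  if (!is.finite(m) || m == 0) {
    stop("input error: zero mean; CV is undefined")
  }
  sd(values) / m
}
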