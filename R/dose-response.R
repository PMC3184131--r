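#' Relative expression from qPCR cycle thresholds (delta-delta-Ct)
#'
#' Converts Ct quadruples to a relative expression ratio, normalizing the
#' target gene to a reference gene (e.g. ribosomal protein L3) in both the
#' treated sample and the untreated control:
#' `2^-((ct_target_sample - ct_ref_sample) - (ct_target_control - ct_ref_control))`.
#' Amplification efficiency is assumed to be exactly 2 (perfect doubling per
#' cycle); no standard-curve correction is applied.
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_control,ct_ref_control
#'   Numeric vectors of cycle-threshold values (recycled to a common length).
#' @return Numeric vector of unitless expression ratios (treated / control).
#' @examples
#' relative_expression(25, 20, 22, 20)  # ddCt = 3 -> 0.125
#' @export
relative_expression <- function(ct_target_sample, ct_ref_sample,
                                ct_target_control, ct_ref_control) {
  cts <- cbind(ct_target_sample, ct_ref_sample, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (cts[, 1L] - cts[, 2L]) - (cts[, 3L] - cts[, 4L])
  unname(2^(-ddct))
}

#' Exponential knockdown dose-response model
#'
#' Constructs a fitted-model object for the decay model
#' `y(x) = a * exp(-b * x)`, where `x` is the injected siRNA concentration in
#' micromolar and `y` the relative target mRNA level (treated / control).
#' Usually produced by [fit_decay()]; calling this directly lets you work
#' with published parameter values.
#'
#' @param a Amplitude: model value at concentration 0 (unitless ratio).
#' @param b Decay rate per micromolar.
#' @param R Correlation of the fit on the log scale (optional, magnitude).
#' @param n Number of points behind the fit (optional).
#' @param data The fitted points, as a tibble with `conc` and `rel_mrna`
#'   (optional).
#' @return An object of class `decay_fit`.
#' @examples
#' effective_concentration(decay_fit(a = 0.9, b = 0.028))
#' @export
decay_fit <- function(a, b, R = NA_real_, n = NA_integer_, data = NULL) {
  stopifnot(is.finite(a), is.finite(b))
  structure(list(a = a, b = b, R = R, n = as.integer(n), data = data),
            class = "decay_fit")
}

#' Fit the exponential knockdown model to dose-response data
#'
#' Ordinary least squares of `log(rel_mrna)` on concentration (exact,
#' closed-form, deterministic): `a = exp(intercept)`, `b = -slope`. The fit
#' correlation `R` is the magnitude of the Pearson correlation between the
#' log-scale responses and the fitted line.
#'
#' @param data Data frame with one row per observation. Columns `conc`
#'   (micromolar) and `rel_mrna` (ratio, must be > 0) are used; `conc_uM` is
#'   accepted as an alias for `conc`.
#' @return A [decay_fit()] object with elements `a`, `b`, `R`, `n` and the
#'   fitted points in `$data`.
#' @examples
#' pts <- simulate_dose_data(a = 0.9, b = 0.028, doses = c(0, 25, 50, 100),
#'                           replicates = 1, noise_sigma = 0, seed = 1)
#' fit_decay(pts)
#' @export
fit_decay <- function(data) {
  stopifnot(is.data.frame(data))
  if (!"conc" %in% names(data) && "conc_uM" %in% names(data)) {
    data$conc <- data$conc_uM
  }
  if (!all(c("conc", "rel_mrna") %in% names(data))) {
    stop("data must have columns 'conc' (or 'conc_uM') and 'rel_mrna'")
  }
  pts <- tibble::tibble(conc = as.numeric(data$conc),
                        rel_mrna = as.numeric(data$rel_mrna))
  if (any(!is.finite(pts$conc)) || any(!is.finite(pts$rel_mrna))) {
    stop("non-finite dose or response value")
  }
  bad <- pts$rel_mrna <= 0
  if (any(bad)) {
    stop("rel_mrna must be > 0 for the log-linear fit; offending point(s) at conc ",
         paste(pts$conc[bad], collapse = ", "))
  }
  if (nrow(pts) < 3L) stop("need at least 3 points to fit the decay model")
  if (length(unique(pts$conc)) < 2L) {
    stop("need at least 2 distinct concentrations to fit the decay model")
  }
  fit <- stats::lm(log(rel_mrna) ~ conc, data = pts)
  co <- stats::coef(fit)
  R <- if (stats::sd(stats::fitted(fit)) == 0) NA_real_ else
    abs(stats::cor(log(pts$rel_mrna), stats::fitted(fit)))
  decay_fit(a = unname(exp(co[[1L]])), b = unname(-co[[2L]]),
            R = R, n = nrow(pts), data = pts)
}

#' Effective concentration at a given knockdown level
#'
#' Solves `a * exp(-b * x) = level` for the dose `x`. With the default
#' `level = 0.5` this is the median effective concentration: the dose at
#' which the model predicts the target mRNA at half the control level.
#'
#' @param fit A [decay_fit()] object.
#' @param level Relative mRNA threshold in `(0, a)` (default 0.5).
#' @return The dose in micromolar: `log(a / level) / b`.
#' @examples
#' effective_concentration(decay_fit(0.9, 0.028))  # ~21 uM
#' @export
effective_concentration <- function(fit, level = 0.5) {
  stopifnot(inherits(fit, "decay_fit"), length(level) == 1L, level > 0)
  if (fit$b <= 0) stop("decay rate b must be > 0: the model never decreases")
  if (fit$a <= level) {
    stop("amplitude a = ", signif(fit$a, 4), " <= level = ", level,
         ": the model never reaches the threshold at a non-negative dose")
  }
  log(fit$a / level) / fit$b
}

#' Predict relative mRNA level at given doses
#'
#' @param object A [decay_fit()] object.
#' @param conc Numeric vector of doses in micromolar.
#' @param ... Unused.
#' @return Numeric vector `a * exp(-b * conc)`.
#' @export
predict.decay_fit <- function(object, conc, ...) {
  object$a * exp(-object$b * conc)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("Exponential knockdown fit: y = %.4g * exp(-%.4g * x)\n", x$a, x$b))
  if (is.finite(x$R)) cat(sprintf("  R = %.4f (log scale), n = %d\n", x$R, x$n))
  if (x$b > 0 && x$a > 0.5) {
    cat(sprintf("  median effective concentration: %.1f uM\n",
                effective_concentration(x, 0.5)))
  }
  invisible(x)
}

#' Tidy a decay fit into a one-row-per-parameter tibble
#'
#' @param x A [decay_fit()] object.
#' @param ... Unused.
#' @return Tibble with columns `term` (`"a"`, `"b"`) and `estimate`.
#' @exportS3Method generics::tidy
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b"), estimate = c(x$a, x$b))
}

#' One-row model summary of a decay fit
#'
#' @param x A [decay_fit()] object.
#' @param ... Unused.
#' @return One-row tibble with `a`, `b`, `R`, `n` and `ec50` (`NA` when the
#'   model never reaches half the control level).
#' @exportS3Method generics::glance
glance.decay_fit <- function(x, ...) {
  ec <- if (x$b > 0 && x$a > 0.5) effective_concentration(x, 0.5) else NA_real_
  tibble::tibble(a = x$a, b = x$b, R = x$R, n = x$n, ec50 = ec)
}

#' Observations with fitted values and residuals
#'
#' @param x A fitted [decay_fit()] (must carry its data).
#' @param ... Unused.
#' @return The fitted points with `fitted` (model scale) and `log_residual`
#'   (`log(rel_mrna) - log(fitted)`, the scale the fit minimizes) appended.
#' @exportS3Method generics::augment
augment.decay_fit <- function(x, ...) {
  if (is.null(x$data)) stop("this decay_fit carries no data to augment")
  dplyr::mutate(x$data, fitted = predict(x, .data$conc),
                log_residual = log(.data$rel_mrna) - log(.data$fitted))
}

#' Plot dose-response points with the fitted decay curve
#'
#' @param object A fitted [decay_fit()] carrying its data.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.decay_fit <- function(object, ...) {
  if (is.null(object$data)) stop("this decay_fit carries no data to plot")
  grid <- tibble::tibble(conc = seq(0, max(object$data$conc), length.out = 200))
  grid$rel_mrna <- predict(object, grid$conc)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc, y = .data$rel_mrna)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "injected siRNA (µM)", y = "relative target mRNA",
      title = sprintf("y = %.3g e^(-%.3g x)", object$a, object$b)) +
    ggplot2::theme_minimal()
}

#' Read a dose-response table from a delimited file
#'
#' Accepts either ratio data — columns `conc_uM` and `rel_mrna` — or raw Ct
#' quadruples — columns `conc_uM`, `ct_target`, `ct_ref`, `ct_target_control`,
#' `ct_ref_control` — in which case relative expression is computed row-wise
#' with [relative_expression()].
#'
#' @param path Path to a CSV file.
#' @return Tibble with columns `conc` and `rel_mrna`, ready for [fit_decay()].
#' @export
read_dose_table <- function(path) {
  if (!file.exists(path)) stop("dose table not found: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE)
  ct_cols <- c("ct_target", "ct_ref", "ct_target_control", "ct_ref_control")
  if (!"conc_uM" %in% names(tab)) stop("dose table must have a conc_uM column")
  if ("rel_mrna" %in% names(tab)) {
    return(tibble::tibble(conc = tab$conc_uM, rel_mrna = tab$rel_mrna))
  }
  if (all(ct_cols %in% names(tab))) {
    return(tibble::tibble(
      conc = tab$conc_uM,
      rel_mrna = relative_expression(tab$ct_target, tab$ct_ref,
                                     tab$ct_target_control, tab$ct_ref_control)))
  }
  stop("dose table must have either a rel_mrna column or the four Ct columns (",
       paste(ct_cols, collapse = ", "), ")")
}
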