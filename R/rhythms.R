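#' Relative expression by the delta-delta-Ct method
#'
#' Computes per-record `dCt = ct_target - ct_housekeeping`, references it to
#' the mean control-ZT0 `dCt` of the same gene, and converts to fold change
#' `2^(-ddCt)`. Records lacking a housekeeping Ct are dropped with a reason
#' column.
#'
#' @param records Tibble with columns `gene`, `genotype`, `zt`, `replicate`,
#'   `ct_target`, `ct_housekeeping` (e.g. Gapdh).
#' @param reference Optional named numeric vector of reference `dCt` per
#'   gene; defaults to the mean `dCt` of `genotype == "Ctrl"`, `zt == 0`
#'   rows of each gene.
#' @return Input tibble with added `dct`, `ddct`, `fold` columns (dropped
#'   records are excluded; a message reports how many).
#' @export
delta_delta_ct <- function(records, reference = NULL) {
  stopifnot(all(c("gene", "genotype", "zt", "ct_target", "ct_housekeeping")
                %in% names(records)))
  bad <- !is.finite(records$ct_housekeeping) | !is.finite(records$ct_target)
  if (any(bad)) {
    message(sprintf("dropping %d record(s) without finite Ct values", sum(bad)))
    records <- records[!bad, ]
  }
  records$dct <- records$ct_target - records$ct_housekeeping
  if (is.null(reference)) {
    ref_tbl <- records |>
      dplyr::filter(.data$genotype == "Ctrl", .data$zt == 0) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(ref_dct = mean(.data$dct), .groups = "drop")
  } else {
    ref_tbl <- tibble::tibble(gene = names(reference), ref_dct = reference)
  }
  out <- dplyr::left_join(records, ref_tbl, by = "gene")
  if (any(is.na(out$ref_dct))) {
    stop("no control ZT0 reference for gene(s): ",
         paste(unique(out$gene[is.na(out$ref_dct)]), collapse = ", "),
         call. = FALSE)
  }
  out$ddct <- out$dct - out$ref_dct
  out$fold <- 2^(-out$ddct)
  dplyr::select(out, -"ref_dct")
}

#' Fixed-period cosinor fit
#'
#' Least-squares fit of `y = M + A cos(2 pi (t - phi) / period)` via the
#' linearization `y ~ cos(wt) + sin(wt)`; the amplitude is
#' `sqrt(beta^2 + gamma^2)` (non-negative by construction) and the acrophase
#' `phi` is the clock time of the fitted peak, reported modulo the period.
#' The cosine model is compared against a horizontal line with the
#' extra-sum-of-squares F test (`F = ((rss_flat - rss_cos)/2) /
#' (rss_cos/(n-3))`, p from `F(2, n-3)`), and against a straight line whose
#' slope t-test feeds the model selection rule. Residual normality is
#' assessed with the D'Agostino-Pearson K2 omnibus test when at least 8
#' residuals are available.
#'
#' @param times Sampling times (h), e.g. ZT 0/6/12/18 with replicates.
#' @param values Measured expression (fold change or arbitrary units).
#' @param period Fixed period (h), default 24.
#' @return A `cosinor_fit` object with fields `baseline`, `amplitude`,
#'   `acrophase`, `period`, `rss_cosine`, `rss_flat`, `rss_linear`,
#'   `f_stat`, `p_vs_flat`, `slope`, `p_linear`, `k2_stat`, `p_normality`,
#'   `normality_skipped`, `selected_model`, `n`, `data`.
#' @export
cosinor_fit <- function(times, values, period = 24) {
  stopifnot(length(times) == length(values), period > 0)
  ok <- is.finite(times) & is.finite(values)
  times <- times[ok]; values <- values[ok]
  n <- length(values)
  if (n <= 3) stop("cosinor fit is underdetermined with n <= 3", call. = FALSE)
  if (length(unique(times)) < 4) {
    stop("need at least 4 distinct time points", call. = FALSE)
  }
  if (max(times) - min(times) < period) {
    # allowed, but sampling under one full period is flagged in the object
    partial_span <- TRUE
  } else partial_span <- FALSE

  w <- 2 * pi / period
  X <- cbind(1, cos(w * times), sin(w * times))
  coefs <- stats::lm.fit(X, values)$coefficients
  m <- coefs[1]; beta <- coefs[2]; gamma <- coefs[3]
  fitted_cos <- X %*% coefs
  rss_cos <- sum((values - fitted_cos)^2)
  rss_flat <- sum((values - mean(values))^2)
  lin <- stats::lm(values ~ times)
  rss_lin <- sum(stats::residuals(lin)^2)
  slope <- stats::coef(lin)[2]
  p_lin <- summary(lin)$coefficients[2, 4]

  amplitude <- sqrt(beta^2 + gamma^2)
  # y = M + A cos(w t - delta), delta = atan2(gamma, beta); peak at t = delta/w
  acrophase <- (atan2(gamma, beta) / w) %% period

  f_stat <- ((rss_flat - rss_cos) / 2) / (rss_cos / (n - 3))
  p_vs_flat <- stats::pf(f_stat, 2, n - 3, lower.tail = FALSE)

  res <- as.numeric(values - fitted_cos)
  if (n >= 8 && stats::sd(res) > 0) {
    k2 <- dagostino_k2(res)
    k2_stat <- k2$k2; p_norm <- k2$p; norm_skip <- FALSE
  } else {
    k2_stat <- NA_real_; p_norm <- NA_real_; norm_skip <- TRUE
  }

  fit <- structure(
    list(
      baseline = unname(m), amplitude = unname(amplitude),
      acrophase = unname(acrophase), period = period,
      rss_cosine = rss_cos, rss_flat = rss_flat, rss_linear = rss_lin,
      f_stat = unname(f_stat), p_vs_flat = unname(p_vs_flat),
      slope = unname(slope), p_linear = unname(p_lin),
      k2_stat = k2_stat, p_normality = p_norm,
      normality_skipped = norm_skip, partial_span = partial_span,
      n = n, data = tibble::tibble(time = times, value = values,
                                   fitted = as.numeric(fitted_cos))
    ),
    class = "cosinor_fit"
  )
  fit$selected_model <- select_model(fit)
  fit
}

#' Model selection: cosine vs linear vs flat
#'
#' The 24 h cosine is selected when the extra-sum-of-squares F test against
#' the flat line has `p < 0.05`; otherwise a straight line is selected when
#' its slope is significant at the same level; otherwise the series is
#' called flat (arrhythmic).
#'
#' @param fit A [cosinor_fit()].
#' @param alpha Significance level.
#' @return `"cosine"`, `"linear"` or `"flat"`.
#' @export
select_model <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "cosinor_fit"))
  if (fit$p_vs_flat < alpha) "cosine"
  else if (fit$p_linear < alpha) "linear"
  else "flat"
}

#' D'Agostino-Pearson K2 omnibus normality test
#'
#' Combines the standardized sample skewness (Z1) and kurtosis (Z2)
#' transforms into `K2 = Z1^2 + Z2^2`, chi-squared with 2 df under
#' normality. Requires `n >= 8`.
#'
#' @param x Numeric sample.
#' @return List with `k2`, `p`, `z_skew`, `z_kurt`.
#' @export
dagostino_k2 <- function(x) {
  n <- length(x)
  if (n < 8) stop("K2 test requires n >= 8", call. = FALSE)
  x <- x - mean(x)
  m2 <- mean(x^2); m3 <- mean(x^3); m4 <- mean(x^4)
  if (m2 <= 0) stop("degenerate (constant) sample", call. = FALSE)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2

  # skewness transform (D'Agostino 1970)
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z1 <- delta * asinh(y / alpha)

  # kurtosis transform (Anscombe & Glynn 1983)
  e_g2 <- 3 * (n - 1) / (n + 1)
  var_g2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xq <- (g2 - e_g2) / sqrt(var_g2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * a)) -
           ((1 - 2 / a) / (1 + xq * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))

  k2 <- z1^2 + z2^2
  list(k2 = k2, p = stats::pchisq(k2, df = 2, lower.tail = FALSE),
       z_skew = z1, z_kurt = z2)
}

#' Residual normality check of a cosinor fit
#' @param fit A [cosinor_fit()].
#' @return Tibble `k2`, `p`, `skipped`.
#' @export
residual_normality <- function(fit) {
  stopifnot(inherits(fit, "cosinor_fit"))
  tibble::tibble(k2 = fit$k2_stat, p = fit$p_normality,
                 skipped = fit$normality_skipped)
}

#' @export
print.cosinor_fit <- function(x, ...) {
  cat(sprintf(
    "<cosinor_fit> n = %d, baseline %.4g, amplitude %.4g, acrophase ZT%.2f (period %g h)\n  model: %s (F = %.3g, p vs flat = %.3g)\n",
    x$n, x$baseline, x$amplitude, x$acrophase, x$period,
    x$selected_model, x$f_stat, x$p_vs_flat
  ))
  invisible(x)
}

#' @method tidy cosinor_fit
#' @export
tidy.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    term = c("baseline", "amplitude", "acrophase"),
    estimate = c(x$baseline, x$amplitude, x$acrophase)
  )
}

#' @method glance cosinor_fit
#' @export
glance.cosinor_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, period = x$period,
    rss_cosine = x$rss_cosine, rss_flat = x$rss_flat,
    rss_linear = x$rss_linear,
    f_stat = x$f_stat, p_vs_flat = x$p_vs_flat,
    p_linear = x$p_linear,
    k2_stat = x$k2_stat, p_normality = x$p_normality,
    selected_model = x$selected_model
  )
}

#' @method autoplot cosinor_fit
#' @export
autoplot.cosinor_fit <- function(object, ...) {
  grid <- tibble::tibble(time = seq(0, object$period, length.out = 241))
  w <- 2 * pi / object$period
  grid$fitted <- object$baseline +
    object$amplitude * cos(w * (grid$time - object$acrophase))
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted),
                       colour = "blue") +
    ggplot2::labs(x = "Zeitgeber time (h)", y = "relative expression")
}

#' Per-ZT genotype comparisons with Holm-Sidak correction
#'
#' For each gene, runs one two-sample t-test per Zeitgeber time comparing
#' genotypes, then applies the Holm-Sidak step-down correction over the ZT
#' family of that gene. ZTs with a missing arm are skipped.
#'
#' @param expression Tibble with columns `gene`, `genotype`
#'   (`"Ctrl"`/`"cKO"`), `zt`, `value`.
#' @return Tibble `gene`, `zt`, `n_ctrl`, `n_cko`, `t`, `p`, `p_adj`,
#'   `skipped`.
#' @export
per_zt_genotype_tests <- function(expression) {
  stopifnot(all(c("gene", "genotype", "zt", "value") %in% names(expression)))
  out <- expression |>
    dplyr::group_by(.data$gene, .data$zt) |>
    dplyr::group_modify(function(df, key) {
      a <- df$value[df$genotype == "Ctrl"]
      b <- df$value[df$genotype == "cKO"]
      if (length(a) >= 2 && length(b) >= 2) {
        tt <- stats::t.test(a, b)
        tibble::tibble(n_ctrl = length(a), n_cko = length(b),
                       t = unname(tt$statistic), p = tt$p.value,
                       skipped = FALSE)
      } else {
        tibble::tibble(n_ctrl = length(a), n_cko = length(b),
                       t = NA_real_, p = NA_real_, skipped = TRUE)
      }
    }) |>
    dplyr::ungroup()
  out |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(p_adj = p_adjust_holm_sidak(.data$p)) |>
    dplyr::ungroup()
}

#' Fit cosinor models for every gene x genotype series
#'
#' @param expression Tibble with `gene`, `genotype`, `zt`, `value`.
#' @param period Fixed period (h).
#' @return Tibble `gene`, `genotype`, one `fit` list-column plus unnested
#'   glance columns.
#' @export
cosinor_by_gene <- function(expression, period = 24) {
  expression |>
    dplyr::group_by(.data$gene, .data$genotype) |>
    dplyr::group_modify(function(df, key) {
      fit <- cosinor_fit(df$zt, df$value, period)
      dplyr::bind_cols(tibble::tibble(fit = list(fit)),
                       tidyr::pivot_wider(tidy(fit), names_from = "term",
                                          values_from = "estimate"),
                       glance(fit)[, c("p_vs_flat", "selected_model")])
    }) |>
    dplyr::ungroup()
}
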