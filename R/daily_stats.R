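#' Peak firing rate in the preferred stimulus half-cycle
#'
#' Maximum PSTH bin over the white half `[0, 1)` for ON cells and the black
#' half `[1, 2)` for OFF cells. ON-OFF cells have no single preferred half
#' and are excluded from peak analysis by contract.
#'
#' @param x A `psth`.
#' @param polarity `"ON"` or `"OFF"`.
#' @return Peak rate (spikes/s).
#' @export
peak_response <- function(x, polarity) {
  stopifnot(inherits(x, "psth"))
  if (!polarity %in% c("ON", "OFF")) {
    stop("peak analysis is restricted to ON and OFF cells", call. = FALSE)
  }
  n <- length(x$rates)
  half <- n %/% 2
  idx <- if (polarity == "ON") seq_len(half) else (half + 1):n
  max(x$rates[idx])
}

#' Genotype comparison of peak rates by Kolmogorov-Smirnov test
#'
#' Two-sided two-sample KS test on cell-level peak rates within each
#' (cluster, ZT, CT) stratum. Exact small-sample p-values are used when
#' `stats::ks.test` provides them (no ties, small n).
#'
#' @param peaks Tibble of peak records with columns `cluster`, `zt`, `ct`,
#'   `genotype` (`"Ctrl"`/`"cKO"`) and `peak_rate`.
#' @return Tibble `cluster`, `zt`, `ct`, `n_ctrl`, `n_cko`, `D`, `p`
#'   (`NA` with fewer than 2 cells in an arm; stratum flagged in `skipped`).
#' @export
genotype_peak_test <- function(peaks) {
  stopifnot(all(c("cluster", "zt", "ct", "genotype", "peak_rate") %in%
                  names(peaks)))
  peaks |>
    dplyr::group_by(.data$cluster, .data$zt, .data$ct) |>
    dplyr::group_modify(function(df, key) {
      a <- df$peak_rate[df$genotype == "Ctrl"]
      b <- df$peak_rate[df$genotype == "cKO"]
      if (length(a) >= 2 && length(b) >= 2) {
        kt <- suppressWarnings(stats::ks.test(a, b))
        tibble::tibble(n_ctrl = length(a), n_cko = length(b),
                       D = unname(kt$statistic), p = kt$p.value,
                       skipped = FALSE)
      } else {
        tibble::tibble(n_ctrl = length(a), n_cko = length(b),
                       D = NA_real_, p = NA_real_, skipped = TRUE)
      }
    }) |>
    dplyr::ungroup()
}

#' One-way ANOVA over Zeitgeber times with Tukey-Kramer post-hoc
#'
#' Tests, within one genotype (and typically one cluster and contrast),
#' whether cell-level peak rates differ across the four ZT groups, followed
#' by Tukey's honest significant differences (Tukey-Kramer for unequal
#' group sizes).
#'
#' @param peaks Tibble with columns `zt` and `peak_rate`. Groups with fewer
#'   than 2 cells are dropped with a warning.
#' @return List with `f`, `p`, `df`, and `tukey`, a tibble
#'   (`comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
zt_anova <- function(peaks) {
  stopifnot(all(c("zt", "peak_rate") %in% names(peaks)))
  sizes <- table(peaks$zt)
  drop <- names(sizes)[sizes < 2]
  if (length(drop) > 0) {
    warning("dropping ZT group(s) with < 2 cells: ",
            paste(drop, collapse = ", "), call. = FALSE)
    peaks <- peaks[!peaks$zt %in% as.numeric(drop), ]
  }
  if (length(unique(peaks$zt)) < 2) {
    stop("need at least 2 ZT groups with >= 2 cells", call. = FALSE)
  }
  peaks$zt_f <- factor(peaks$zt)
  fit <- stats::aov(peak_rate ~ zt_f, data = peaks)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$zt_f
  list(
    f = an[["F value"]][1],
    p = an[["Pr(>F)"]][1],
    df = an[["Df"]],
    tukey = tibble::tibble(
      comparison = rownames(tk),
      diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
      p_adj = tk[, "p adj"]
    )
  )
}

#' Control-normalized peak scatter table
#'
#' Cluster-mean peaks of both genotypes are divided, per Zeitgeber time, by
#' the maximum control cluster-mean peak over the contrasts at that ZT
#' (`variant = "per_zt"`, the default) or by the maximum control peak over
#' the whole day (`variant = "day"`).
#'
#' @param cluster_means Tibble with columns `zt`, `ct`, `genotype`,
#'   `mean_peak` (one row per stratum x genotype; typically per cluster).
#' @param variant Normalization denominator rule.
#' @return Tibble `zt`, `ct`, `norm_ctrl`, `norm_cko`. Strata with a zero
#'   denominator are omitted with a message.
#' @export
normalized_peak_scatter <- function(cluster_means,
                                    variant = c("per_zt", "day")) {
  variant <- match.arg(variant)
  stopifnot(all(c("zt", "ct", "genotype", "mean_peak") %in%
                  names(cluster_means)))
  wide <- tidyr::pivot_wider(cluster_means, names_from = "genotype",
                             values_from = "mean_peak")
  stopifnot(all(c("Ctrl", "cKO") %in% names(wide)))
  denom_tbl <- wide |>
    dplyr::group_by(.data$zt) |>
    dplyr::summarise(denom = max(.data$Ctrl), .groups = "drop")
  if (variant == "day") denom_tbl$denom <- max(denom_tbl$denom)
  out <- dplyr::left_join(wide, denom_tbl, by = "zt")
  bad <- out$denom <= 0
  if (any(bad)) {
    message(sprintf("omitting %d stratum/strata with zero control denominator",
                    sum(bad)))
    out <- out[!bad, ]
  }
  tibble::tibble(
    zt = out$zt, ct = out$ct,
    norm_ctrl = out$Ctrl / out$denom,
    norm_cko = out$cKO / out$denom
  )
}

#' Match unit polarity labels across luminance regimes
#'
#' Joins per-unit polarity calls from the mesopic and photopic recordings of
#' the same retina and categorizes each shared unit as `maintained` (same
#' label in both regimes), `switched` (different labels), or `NA` (no
#' template match in at least one regime).
#'
#' @param calls_mesopic,calls_photopic Tibbles with columns `unit_id`,
#'   `label` (from [classify_polarity()] / [classify_session()]).
#' @return Tibble `unit_id`, `label_mesopic`, `label_photopic`, `category`,
#'   plus `class` = the mesopic label (stratification base).
#' @export
match_units_across_regimes <- function(calls_mesopic, calls_photopic) {
  m <- dplyr::select(calls_mesopic, "unit_id", label_mesopic = "label")
  p <- dplyr::select(calls_photopic, "unit_id", label_photopic = "label")
  pairs <- dplyr::inner_join(m, p, by = "unit_id")
  if (nrow(pairs) == 0) stop("no shared unit ids between regimes", call. = FALSE)
  pairs$category <- dplyr::case_when(
    is.na(pairs$label_mesopic) | is.na(pairs$label_photopic) ~ "NA",
    pairs$label_mesopic == pairs$label_photopic ~ "maintained",
    TRUE ~ "switched"
  )
  pairs$class <- pairs$label_mesopic
  pairs
}

#' Luminance-dependent polarity maintenance table
#'
#' Percentage of cells per polarity class (and genotype, optionally per ZT)
#' that keep the same ON / ON-OFF / OFF label when the ambient luminance is
#' raised from mesopic to photopic. Unmatched (`NA`) cells are counted but
#' excluded from the percentage denominator.
#'
#' @param pairs Tibble from [match_units_across_regimes()], with extra
#'   stratification columns `genotype` (and `zt` when `by = "per_zt"`).
#' @param by `"overall"` or `"per_zt"`.
#' @return Tibble `class`, `genotype` (, `zt`), `n_maintained`, `n_switched`,
#'   `n_na`, `pct_maintained`. Classes with no matched pairs carry
#'   `pct_maintained = NA`.
#' @export
polarity_maintenance <- function(pairs, by = c("overall", "per_zt")) {
  by <- match.arg(by)
  keys <- c("class", "genotype", if (by == "per_zt") "zt")
  stopifnot(all(keys %in% c(names(pairs), "class")))
  pairs <- pairs[!is.na(pairs$class), ]
  pairs |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_maintained = sum(.data$category == "maintained"),
      n_switched = sum(.data$category == "switched"),
      n_na = sum(.data$category == "NA"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      pct_maintained = ifelse(
        .data$n_maintained + .data$n_switched > 0,
        100 * .data$n_maintained / (.data$n_maintained + .data$n_switched),
        NA_real_
      )
    )
}

#' Fisher's exact test on maintained/switched counts
#'
#' Two-sided Fisher exact test on the 2x2 table of (maintained, switched)
#' cells in control vs. conditional-knockout retinae.
#'
#' @param ctrl,cko Length-2 integer vectors `c(maintained, switched)`.
#' @return Tibble `p`, `odds_ratio`, `degenerate` (TRUE with `p = 1` when a
#'   margin of the table is zero).
#' @export
fisher_maintenance_test <- function(ctrl, cko) {
  stopifnot(length(ctrl) == 2, length(cko) == 2,
            all(ctrl >= 0), all(cko >= 0))
  tab <- rbind(ctrl, cko)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("degenerate margin; p = 1", call. = FALSE)
    return(tibble::tibble(p = 1, odds_ratio = NA_real_, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  tibble::tibble(p = ft$p.value, odds_ratio = unname(ft$estimate),
                 degenerate = FALSE)
}

#' Peak record table for the top clusters of a session set
#'
#' Builds the full stratified peak-rate table (unit x cluster x ZT x CT x
#' genotype) for ON and OFF cells of the analysis clusters. Missing strata
#' remain absent rows, never silently imputed.
#'
#' @param sessions List of [rgc_session()] objects (one regime).
#' @param calls Tibble of polarity calls with `unit_id`, `label`, and a
#'   `retina_id` column matching the sessions.
#' @param labels Named integer cluster labels per unit (units of ON and OFF
#'   classes).
#' @param clusters_keep Integer cluster ids to retain (e.g. from
#'   [top_clusters()]); `NULL` keeps all.
#' @param cts Contrasts to evaluate (default protocol contrasts).
#' @return Tibble `unit_id`, `retina_id`, `genotype`, `zt`, `ct`, `cluster`,
#'   `polarity`, `peak_rate`.
#' @export
peak_record_table <- function(sessions, calls, labels, clusters_keep = NULL,
                              cts = NULL) {
  rows <- purrr::map(sessions, function(ss) {
    use_cts <- cts %||% ss$protocol$contrasts
    sess_calls <- calls[calls$retina_id == ss$retina_id &
                          calls$label %in% c("ON", "OFF"), ]
    if (nrow(sess_calls) == 0) return(NULL)
    units <- split(ss$spikes$time, ss$spikes$unit_id)
    purrr::map_dfr(seq_len(nrow(sess_calls)), function(i) {
      uid <- sess_calls$unit_id[i]
      cl <- unname(labels[as.character(uid)])
      if (is.na(cl) || (!is.null(clusters_keep) && !cl %in% clusters_keep)) {
        return(NULL)
      }
      tt <- units[[as.character(uid)]]
      purrr::map_dfr(use_cts, function(ct) {
        ph <- epoch_spikes(tt, ss$protocol, ct)
        pk <- if (nrow(ph) == 0) 0 else {
          peak_response(psth(ph), sess_calls$label[i])
        }
        tibble::tibble(
          unit_id = uid, retina_id = ss$retina_id, genotype = ss$genotype,
          zt = ss$zt, ct = ct, cluster = cl,
          polarity = sess_calls$label[i], peak_rate = pk
        )
      })
    })
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Scatter plot of control-normalized peak responses
#'
#' @param scatter Tibble from [normalized_peak_scatter()].
#' @return A ggplot: cKO (x) vs Ctrl (y) normalized cluster-mean peaks,
#'   colored by ZT, shaped by contrast, with the unity line dashed.
#' @export
plot_peak_scatter <- function(scatter) {
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$norm_cko, y = .data$norm_ctrl,
                               colour = factor(.data$zt),
                               shape = factor(.data$ct))) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "normalized peak (cKO)", y = "normalized peak (Ctrl)",
                  colour = "ZT", shape = "CT")
}
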