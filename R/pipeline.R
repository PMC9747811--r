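#' Pipeline run configuration
#'
#' Validated bag of thresholds and options consumed by [run_pipeline()];
#' every field is range-checked here so that stage code can assume a sane
#' configuration. The configuration is persisted verbatim in the run
#' manifest.
#'
#' @param min_rate Spontaneous rate floor (spikes/s), in `[0, 10]`.
#' @param alpha Responsiveness / significance level, in `(0, 1)`.
#' @param theta Template rejection threshold, in `(0, 1]`.
#' @param k_range Candidate cluster counts.
#' @param var_explained PCA variance rule, in `(0, 1]`.
#' @param normalization `"per_zt"` or `"day"` scatter denominator rule.
#' @param top_n Number of most abundant clusters carried into peak analysis.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_rate = 0.1, alpha = 0.05, theta = 0.25,
                            k_range = 2:20, var_explained = 0.9,
                            normalization = c("per_zt", "day"),
                            top_n = 4, seed = 1) {
  normalization <- match.arg(normalization)
  check <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid config field `%s`: %s", field, msg),
                  call. = FALSE)
  }
  check(is.numeric(min_rate) && min_rate >= 0 && min_rate <= 10,
        "min_rate", "must be in [0, 10]")
  check(is.numeric(alpha) && alpha > 0 && alpha < 1,
        "alpha", "must be in (0, 1)")
  check(is.numeric(theta) && theta > 0 && theta <= 1,
        "theta", "must be in (0, 1]")
  check(all(k_range >= 2), "k_range", "all k must be >= 2")
  check(var_explained > 0 && var_explained <= 1,
        "var_explained", "must be in (0, 1]")
  check(top_n >= 1, "top_n", "must be >= 1")
  structure(
    list(min_rate = min_rate, alpha = alpha, theta = theta,
         k_range = k_range, var_explained = var_explained,
         normalization = normalization, top_n = top_n,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Run the analysis pipeline end to end
#'
#' Classification -> clustering -> daily peak statistics over a list of
#' sessions of one luminance regime, writing tidy per-stage CSV outputs and
#' a JSON manifest. Clustering pools units across genotypes and ZTs within
#' each polarity class, per study design.
#'
#' @param sessions List of [rgc_session()] objects sharing a protocol.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param library Template library.
#' @return Invisibly, a list with `calls`, `clustering` (per polarity),
#'   `peaks`, `genotype_tests`, `manifest_path`.
#' @export
run_pipeline <- function(sessions, out_dir,
                         config = pipeline_config(),
                         library = default_templates(theta = config$theta)) {
  stopifnot(inherits(config, "pipeline_config"), length(sessions) >= 1)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: per-session classification
  calls <- purrr::map_dfr(sessions, function(ss) {
    out <- classify_session(ss, library, min_rate = config$min_rate,
                            alpha = config$alpha)
    out$retina_id <- ss$retina_id
    out$genotype <- ss$genotype
    out$zt <- ss$zt
    out
  })
  message(sprintf("classification: %d units in, %d passed filters, %d labelled",
                  nrow(calls), sum(calls$filter == "passed"),
                  sum(!is.na(calls$label))))
  readr::write_csv(calls, file.path(out_dir, "polarity_calls.csv"))

  # stage 2: clustering per polarity class, pooled across genotype and ZT
  features <- purrr::map(sessions, unit_cycle_features)
  names(features) <- purrr::map_chr(sessions, "retina_id")
  clustering <- list()
  all_labels <- integer(0)
  for (pol in c("ON", "OFF", "ONOFF")) {
    ids <- calls$unit_id[!is.na(calls$label) & calls$label == pol]
    feats <- purrr::map_dfr(features, ~ dplyr::filter(.x, .data$unit_id %in% ids))
    if (nrow(feats) < 5) next
    curves <- curves_to_matrix(feats$cdf, library$grid)
    rownames(curves) <- feats$unit_id
    psths <- stats::setNames(feats$psth, feats$unit_id)
    k_range <- config$k_range[config$k_range < nrow(curves)]
    if (length(k_range) == 0) next
    res <- cluster_polarity_class(curves, psths, polarity = pol,
                                  k_range = k_range, seed = config$seed,
                                  var_explained = config$var_explained)
    clustering[[pol]] <- res
    all_labels <- c(all_labels, res$labels)
    readr::write_csv(res$silhouette_profile,
                     file.path(out_dir, sprintf("silhouette_%s.csv", pol)))
  }
  lab_tbl <- tibble::tibble(unit_id = names(all_labels),
                            cluster = unname(all_labels))
  lab_tbl <- dplyr::left_join(lab_tbl,
                              calls[, c("unit_id", "label", "retina_id",
                                        "genotype", "zt")],
                              by = "unit_id")
  readr::write_csv(lab_tbl, file.path(out_dir, "clusters.csv"))

  # stage 3: peak statistics on the most abundant ON and OFF clusters
  peaks <- NULL
  tests <- NULL
  keep_by_pol <- purrr::imap(clustering[intersect(c("ON", "OFF"),
                                                  names(clustering))],
    function(res, pol) top_clusters(res$summary, n = min(config$top_n,
                                                         nrow(res$summary))))
  if (length(keep_by_pol) > 0) {
    peaks <- purrr::imap_dfr(keep_by_pol, function(keep, pol) {
      res <- clustering[[pol]]
      peak_record_table(sessions, calls[calls$label %in% pol, ],
                        res$labels, clusters_keep = keep)
    })
    if (!is.null(peaks) && nrow(peaks) > 0) {
      readr::write_csv(peaks, file.path(out_dir, "peaks.csv"))
      tests <- genotype_peak_test(peaks)
      readr::write_csv(tests, file.path(out_dir, "genotype_ks_tests.csv"))
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("rgcrhythms")),
    seed = config$seed,
    config = unclass(config),
    n_sessions = length(sessions),
    sessions = purrr::map_chr(sessions, "retina_id"),
    n_units = nrow(calls),
    n_labelled = sum(!is.na(calls$label)),
    k_selected = purrr::map_int(clustering, "k_selected")
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(calls = calls, clustering = clustering, peaks = peaks,
                 genotype_tests = tests, manifest_path = manifest_path))
}
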