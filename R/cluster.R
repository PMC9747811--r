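#' PCA feature extraction from cumulative cycle distributions
#'
#' Mean-centers the curve matrix and retains the smallest number of principal
#' components explaining at least `var_explained` of the total variance.
#' When all curves are identical (zero variance) a single zero-score
#' component is returned.
#'
#' @param curves Numeric matrix, one cumulative distribution per row (or a
#'   list of `cycle_cdf` objects).
#' @param var_explained Fraction of variance the kept components must reach
#'   (default 0.9).
#' @return A `pca_features` object: list with `scores` (units x components),
#'   `loadings`, `center`, `n_components`, `explained_variance_fraction`,
#'   `sdev`.
#' @export
pca_features <- function(curves, var_explained = 0.9) {
  if (is.list(curves) && !is.data.frame(curves) && !is.matrix(curves)) {
    grid <- curves[[1]]$grid
    curves <- curves_to_matrix(curves, grid)
  }
  curves <- as.matrix(curves)
  if (nrow(curves) < 2) stop("need at least 2 curves for PCA", call. = FALSE)
  total_var <- sum(apply(curves, 2, stats::var))
  if (total_var < .Machine$double.eps) {
    scores <- matrix(0, nrow(curves), 1)
    rownames(scores) <- rownames(curves)
    return(structure(
      list(scores = scores, loadings = matrix(0, ncol(curves), 1),
           center = colMeans(curves), n_components = 1L,
           explained_variance_fraction = 1, sdev = 0),
      class = "pca_features"
    ))
  }
  pc <- stats::prcomp(curves, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  k <- which(cum >= var_explained)[1]
  structure(
    list(
      scores = pc$x[, seq_len(k), drop = FALSE],
      loadings = pc$rotation[, seq_len(k), drop = FALSE],
      center = pc$center,
      n_components = as.integer(k),
      explained_variance_fraction = cum[k],
      sdev = pc$sdev
    ),
    class = "pca_features"
  )
}

#' @export
print.pca_features <- function(x, ...) {
  cat(sprintf("<pca_features> %d units, %d component(s), %.1f%% variance\n",
              nrow(x$scores), x$n_components,
              100 * x$explained_variance_fraction))
  invisible(x)
}

#' K-means with seeded restarts and size-ordered labels
#'
#' Runs `stats::kmeans` with `n_restarts` seeded starts, keeps the solution
#' with the lowest total within-cluster sum of squares, and renumbers
#' clusters by descending size (ties by original id) so that cluster 1 is
#' always the most numerous.
#'
#' @param scores Numeric matrix of features (units x components).
#' @param k Number of clusters, >= 2 (or `k = n` for the degenerate
#'   one-point-per-cluster partition).
#' @param seed Integer seed; the call is deterministic given
#'   `(scores, k, seed)`.
#' @param n_restarts Random restarts.
#' @return Integer vector of cluster labels (1..k), named by the score
#'   row names, with attribute `tot_withinss`.
#' @export
kmeans_cluster <- function(scores, k, seed = 1, n_restarts = 10) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  stopifnot(k >= 2, k <= n)
  if (k == n) {
    out <- seq_len(n)
    names(out) <- rownames(scores)
    attr(out, "tot_withinss") <- 0
    return(out)
  }
  labels <- NULL
  for (attempt in 0:4) {
    old <- .Random.seed_save()
    set.seed(derive_seed(seed, attempt))
    fit <- tryCatch(
      stats::kmeans(scores, centers = k, nstart = n_restarts, iter.max = 100),
      error = function(e) NULL
    )
    .Random.seed_restore(old)
    if (!is.null(fit) && all(fit$size > 0)) {
      labels <- fit$cluster
      tot <- fit$tot.withinss
      break
    }
    message("k-means produced an empty/degenerate solution; retrying with new sub-seed")
  }
  if (is.null(labels)) stop("k-means failed after 5 restart attempts", call. = FALSE)
  # renumber by descending size, ties by lower original id
  sizes <- tabulate(labels, nbins = k)
  ord <- order(-sizes, seq_len(k))
  remap <- integer(k); remap[ord] <- seq_len(k)
  out <- remap[labels]
  names(out) <- rownames(scores)
  attr(out, "tot_withinss") <- tot
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Silhouette-based selection of the number of clusters
#'
#' For each candidate `k`, clusters the feature scores with
#' [kmeans_cluster()] and computes the mean silhouette width; the selected
#' `k` maximizes it. When every candidate yields a low silhouette (below
#' `low_confidence_below`), the data are judged weakly clustered and the
#' result is flagged.
#'
#' @param scores Feature matrix (units x components).
#' @param k_range Candidate cluster counts (default 2..20). Candidates with
#'   `k >= n` are skipped with a warning.
#' @param seed Integer seed.
#' @param n_restarts K-means restarts per candidate.
#' @param low_confidence_below Mean-silhouette level under which the
#'   selection is flagged as low confidence (default 0.4: well-separated
#'   structure typically scores above 0.5, an unstructured isotropic cloud
#'   below 0.4).
#' @return List with `k_selected`, `profile` (tibble `k`, `mean_silhouette`),
#'   `low_confidence`.
#' @export
silhouette_select_k <- function(scores, k_range = 2:20, seed = 1,
                                n_restarts = 10, low_confidence_below = 0.4) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  usable <- k_range[k_range < n]
  if (length(usable) < length(k_range)) {
    warning("skipping k >= number of units", call. = FALSE)
  }
  if (length(usable) == 0) stop("no usable k in k_range", call. = FALSE)
  d <- stats::dist(scores)
  prof <- purrr::map_dfr(usable, function(k) {
    labels <- kmeans_cluster(scores, k, seed = derive_seed(seed, k),
                             n_restarts = n_restarts)
    sil <- cluster::silhouette(as.integer(labels), d)
    tibble::tibble(k = k, mean_silhouette = mean(sil[, "sil_width"]))
  })
  best <- prof$k[which.max(prof$mean_silhouette)]
  list(
    k_selected = as.integer(best),
    profile = prof,
    low_confidence = max(prof$mean_silhouette) < low_confidence_below
  )
}

#' Per-cluster normalized mean PSTH and numerosity
#'
#' Each member PSTH is first normalized to its own maximum (so every cell
#' contributes shape, not rate), members are averaged within a cluster, and
#' the cluster mean is renormalized to peak 1. All-zero member PSTHs are
#' excluded from the average but counted in the cluster numerosity.
#'
#' @param labels Integer cluster labels named by unit id (from
#'   [kmeans_cluster()]).
#' @param psths List of `psth` objects named by unit id (every labelled unit
#'   must be present).
#' @return Tibble `cluster`, `numerosity`, `n_averaged`, `mean_psth`
#'   (list-column of numeric rate-shape vectors with peak 1).
#' @export
cluster_summary <- function(labels, psths) {
  stopifnot(!is.null(names(labels)))
  missing <- setdiff(names(labels), names(psths))
  if (length(missing) > 0) {
    stop("PSTH missing for unit(s): ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  purrr::map_dfr(sort(unique(labels)), function(cl) {
    ids <- names(labels)[labels == cl]
    mats <- lapply(ids, function(id) {
      r <- psths[[id]]$rates
      if (max(r) <= 0) NULL else r / max(r)
    })
    dropped <- sum(vapply(mats, is.null, logical(1)))
    if (dropped > 0) {
      message(sprintf("cluster %d: %d all-zero PSTH(s) excluded from average",
                      cl, dropped))
    }
    mats <- purrr::compact(mats)
    mp <- if (length(mats) == 0) NULL else {
      m <- colMeans(do.call(rbind, mats))
      m / max(m)
    }
    tibble::tibble(cluster = cl, numerosity = length(ids),
                   n_averaged = length(mats), mean_psth = list(mp))
  })
}

#' Compare cluster composition between genotypes
#'
#' For each retina, the fraction of its cells (of one polarity class)
#' assigned to each cluster is computed; per cluster, a two-sample t-test
#' compares these per-retina proportions between genotypes, with Holm-Sidak
#' correction over the clusters of that polarity.
#'
#' @param assignments Tibble with columns `unit_id`, `retina_id`, `genotype`
#'   (`"Ctrl"`/`"cKO"`), `cluster`, all of a single polarity class.
#' @return Tibble `cluster`, `mean_prop_ctrl`, `mean_prop_cko`, `t`, `p`,
#'   `p_adj`.
#' @export
compare_cluster_proportions <- function(assignments) {
  stopifnot(all(c("unit_id", "retina_id", "genotype", "cluster") %in%
                  names(assignments)))
  if (length(unique(assignments$genotype)) < 2) {
    stop("both genotypes must be present", call. = FALSE)
  }
  per_gt <- dplyr::count(assignments, .data$retina_id, .data$genotype,
                         name = "n_total")
  if (any(table(per_gt$genotype) < 2)) {
    stop("need at least 2 retinae per genotype", call. = FALSE)
  }
  counts <- dplyr::count(assignments, .data$retina_id, .data$genotype,
                         .data$cluster)
  grid <- tidyr::crossing(
    dplyr::distinct(assignments, .data$retina_id, .data$genotype),
    cluster = sort(unique(assignments$cluster))
  )
  props <- dplyr::left_join(grid, counts,
                            by = c("retina_id", "genotype", "cluster"))
  props$n <- dplyr::coalesce(props$n, 0L)
  props <- dplyr::left_join(props, per_gt, by = c("retina_id", "genotype"))
  props <- dplyr::mutate(props, prop = .data$n / .data$n_total)

  out <- props |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      mean_prop_ctrl = mean(.data$prop[.data$genotype == "Ctrl"]),
      mean_prop_cko = mean(.data$prop[.data$genotype == "cKO"]),
      t = tryCatch(stats::t.test(
        .data$prop[.data$genotype == "Ctrl"],
        .data$prop[.data$genotype == "cKO"])$statistic,
        error = function(e) NA_real_),
      p = tryCatch(stats::t.test(
        .data$prop[.data$genotype == "Ctrl"],
        .data$prop[.data$genotype == "cKO"])$p.value,
        error = function(e) 1),
      .groups = "drop"
    )
  out$t <- unname(out$t)
  out$p_adj <- p_adjust_holm_sidak(out$p)
  out
}

#' Most abundant clusters
#'
#' @param numerosity Named (by cluster id) or plain integer vector of cluster
#'   sizes, or a [cluster_summary()] tibble.
#' @param n Number of clusters to return (default 4, the per-polarity set
#'   carried into the peak analysis).
#' @return Integer cluster ids of the `n` largest clusters, ties broken by
#'   lower id. Fewer clusters than `n` returns all with a warning.
#' @export
top_clusters <- function(numerosity, n = 4) {
  if (is.data.frame(numerosity)) {
    ids <- numerosity$cluster
    sizes <- numerosity$numerosity
  } else {
    sizes <- as.numeric(numerosity)
    ids <- if (!is.null(names(numerosity))) as.integer(names(numerosity))
           else seq_along(sizes)
  }
  if (length(ids) < n) {
    warning("fewer clusters than requested; returning all", call. = FALSE)
    n <- length(ids)
  }
  ids[order(-sizes, ids)][seq_len(n)]
}

#' Cluster one polarity class end-to-end
#'
#' Pools the cumulative distributions of all classified units of one
#' polarity (across genotypes and Zeitgeber times, by design), extracts PCA
#' features, selects the number of clusters by silhouette, and summarises
#' cluster PSTHs and sizes.
#'
#' @param curves Matrix (units x grid) or list of `cycle_cdf` of one
#'   polarity class.
#' @param psths Named list of `psth` objects for the same units.
#' @param polarity Class label being clustered (metadata).
#' @param k_range,seed,n_restarts,var_explained Passed through.
#' @return A `clustering_result`: list with `polarity`, `pca`, `k_selected`,
#'   `silhouette_profile`, `low_confidence`, `labels` (named integer
#'   vector), `summary` (tibble from [cluster_summary()]), `seed`.
#' @export
cluster_polarity_class <- function(curves, psths, polarity = "ON",
                                   k_range = 2:20, seed = 1,
                                   n_restarts = 10, var_explained = 0.9) {
  pf <- pca_features(curves, var_explained)
  sel <- silhouette_select_k(pf$scores, k_range, seed = seed,
                             n_restarts = n_restarts)
  labels <- kmeans_cluster(pf$scores, sel$k_selected,
                           seed = derive_seed(seed, sel$k_selected),
                           n_restarts = n_restarts)
  summ <- cluster_summary(labels, psths)
  structure(
    list(
      polarity = polarity, pca = pf, k_selected = sel$k_selected,
      silhouette_profile = sel$profile, low_confidence = sel$low_confidence,
      labels = labels, summary = summ, seed = seed
    ),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "<clustering_result> %s: %d units, k = %d (mean silhouette %.3f%s), %d PCA component(s)\n",
    x$polarity, length(x$labels), x$k_selected,
    max(x$silhouette_profile$mean_silhouette),
    if (x$low_confidence) ", low confidence" else "",
    x$pca$n_components
  ))
  invisible(x)
}

#' Silhouette profile plot
#' @param object A `clustering_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clustering_result
#' @export
autoplot.clustering_result <- function(object, ...) {
  ggplot2::ggplot(object$silhouette_profile,
                  ggplot2::aes(x = .data$k, y = .data$mean_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_selected,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "number of clusters k", y = "mean silhouette width",
                  title = paste0(object$polarity, " RGCs"))
}
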