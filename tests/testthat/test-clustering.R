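test_that("PCA feature extraction honours the 90% variance rule", {
  # identical curves: degenerate single zero component
  m0 <- matrix(rep(seq(0, 1, length.out = 50), 10), 10, byrow = TRUE)
  pf0 <- pca_features(m0)
  expect_equal(pf0$n_components, 1L)
  expect_true(all(pf0$scores == 0))
  # variation along one direction: a single component carries everything
  base <- seq(0, 1, length.out = 50)
  m1 <- t(sapply(seq(0, 1, length.out = 12), function(a) base * a))
  pf1 <- pca_features(m1)
  expect_equal(pf1$n_components, 1L)
  expect_gte(pf1$explained_variance_fraction, 1 - 1e-12)
  # random matrix: kept components explain at least 90% of total variance
  withr::with_seed(13, mr <- matrix(rnorm(100 * 200), 100, 200))
  pfr <- pca_features(mr)
  expect_gte(pfr$explained_variance_fraction, 0.9)
  tot <- sum(apply(mr, 2, var))
  kept <- sum(apply(pfr$scores, 2, var))
  expect_lte((tot - kept) / tot, 0.1)
  expect_error(pca_features(m1[1, , drop = FALSE]), "at least 2")
})

test_that("silhouette selection finds the true number of separated clouds", {
  withr::with_seed(31, {
    two <- rbind(matrix(rnorm(100, 0, 0.05), 50, 2),
                 matrix(rnorm(100, 3, 0.05), 50, 2))
    centers <- rbind(c(0, 0), c(1, 0), c(0, 1))
    three <- do.call(rbind, lapply(1:3, function(i) {
      sweep(matrix(rnorm(80, 0, 0.01), 40, 2), 2, centers[i, ], `+`)
    }))
    blob <- matrix(rnorm(160), 80, 2)
  })
  s2 <- silhouette_select_k(two, k_range = 2:8, seed = 1)
  expect_equal(s2$k_selected, 2L)
  expect_false(s2$low_confidence)
  s3 <- silhouette_select_k(three, k_range = 2:8, seed = 1)
  expect_equal(s3$k_selected, 3L)
  # single isotropic cloud: all silhouettes low, flagged
  sb <- silhouette_select_k(blob, k_range = 2:8, seed = 1)
  expect_true(sb$low_confidence)
  expect_warning(silhouette_select_k(two[1:5, ], k_range = 2:8, seed = 1),
                 "skipping")
})

test_that("k-means is deterministic, size-ordered, and recovers separated clouds", {
  withr::with_seed(41, {
    x <- rbind(matrix(rnorm(120, 0, 0.1), 60, 2),
               matrix(rnorm(60, 5, 0.1), 30, 2))
  })
  rownames(x) <- sprintf("u%02d", seq_len(nrow(x)))
  l1 <- kmeans_cluster(x, 2, seed = 7)
  l2 <- kmeans_cluster(x, 2, seed = 7)
  expect_identical(l1, l2)
  # ground-truth partition up to relabeling; cluster 1 is the larger one
  expect_true(all(l1[1:60] == 1))
  expect_true(all(l1[61:90] == 2))
  # k = n: every point its own cluster
  sm <- x[1:6, ]
  expect_equal(sort(unname(kmeans_cluster(sm, 6, seed = 1))), 1:6)
})

test_that("cluster summaries are normalized to unit peak", {
  mk_psth <- function(rates) structure(
    list(bin_width = 0.01, rates = rates, n_trials = 20), class = "psth")
  psths <- list(
    a = mk_psth(c(2, 8, 4, 0)), b = mk_psth(c(2, 8, 4, 0)),
    c = mk_psth(c(0, 1, 5, 3)), z = mk_psth(rep(0, 4))
  )
  labels <- c(a = 1L, b = 1L, c = 2L, z = 2L)
  expect_message(summ <- cluster_summary(labels, psths), "all-zero")
  expect_equal(summ$numerosity, c(2, 2))
  expect_equal(summ$n_averaged, c(2, 1))
  # identical members: cluster curve equals the member's normalized PSTH
  expect_equal(summ$mean_psth[[1]], c(2, 8, 4, 0) / 8)
  # single effective member
  expect_equal(summ$mean_psth[[2]], c(0, 1, 5, 3) / 5)
  expect_true(all(vapply(summ$mean_psth, max, numeric(1)) == 1))
  expect_error(cluster_summary(c(q = 1L), psths), "missing")
})

test_that("genotype composition tests are calibrated and detect enrichment", {
  # identical per-retina proportion vectors in both genotypes: all p_adj = 1
  assign_even <- tidyr::crossing(retina_id = sprintf("r%d", 1:6),
                                 cluster = 1:3, rep = 1:10)
  assign_even$genotype <- ifelse(assign_even$retina_id %in%
                                   sprintf("r%d", 1:3), "Ctrl", "cKO")
  assign_even$unit_id <- seq_len(nrow(assign_even))
  out <- compare_cluster_proportions(assign_even)
  expect_true(all(out$p_adj == 1))
  # per-retina proportions sum to 1: mean proportions over clusters do too
  expect_equal(sum(out$mean_prop_ctrl), 1)
  expect_equal(sum(out$mean_prop_cko), 1)

  # one cluster enriched ~3x in cKO with 10 retinae per arm
  withr::with_seed(55, {
    rows <- purrr::map_dfr(1:20, function(r) {
      gt <- if (r <= 10) "Ctrl" else "cKO"
      p <- if (gt == "Ctrl") c(0.6, 0.3, 0.1) else c(0.4, 0.3, 0.3)
      n <- stats::rmultinom(1, 100, p)[, 1]
      tibble::tibble(retina_id = sprintf("r%02d", r), genotype = gt,
                     cluster = rep(1:3, n))
    })
  })
  rows$unit_id <- seq_len(nrow(rows))
  res <- compare_cluster_proportions(rows)
  expect_lt(res$p_adj[res$cluster == 3], 0.05)
  expect_gt(res$p_adj[res$cluster == 2], 0.05)
  expect_error(compare_cluster_proportions(rows[rows$genotype == "Ctrl", ]),
               "both genotypes")
})

test_that("top clusters are chosen by numerosity with lower-id tie-break", {
  expect_equal(top_clusters(c(50, 40, 30, 20, 10)), 1:4)
  expect_equal(top_clusters(c(50, 20, 30, 20, 10)), c(1, 3, 2, 4))
  expect_equal(top_clusters(c(10, 50, 10, 5), n = 1), 2)
  expect_warning(got <- top_clusters(c(9, 7), n = 4), "fewer")
  expect_equal(got, 1:2)
})

test_that("end-to-end polarity-class clustering is reproducible", {
  sess <- simulate_session(counts = c(ON = 60), models = on_four_kernel_models(),
                           effects = null_effects(),
                           protocol = quick_protocol(), seed = 19)
  feats <- unit_cycle_features(sess)
  curves <- do.call(rbind, lapply(feats$cdf, function(x) x$values))
  rownames(curves) <- feats$unit_id
  psths <- stats::setNames(feats$psth, feats$unit_id)
  r1 <- cluster_polarity_class(curves, psths, "ON", k_range = 2:6, seed = 3)
  r2 <- cluster_polarity_class(curves, psths, "ON", k_range = 2:6, seed = 3)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$k_selected, r2$k_selected)
  expect_equal(sum(r1$summary$numerosity), length(r1$labels))
})
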