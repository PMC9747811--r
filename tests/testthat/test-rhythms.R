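test_that("delta-delta-Ct fold changes follow the definition", {
  rec <- tibble::tibble(
    gene = "Per1", genotype = c("Ctrl", "Ctrl", "cKO", "cKO"),
    zt = c(0, 6, 0, 6), replicate = 1,
    ct_target = c(25, 26, 23, 24.5), ct_housekeeping = 20
  )
  out <- delta_delta_ct(rec)
  # reference dCt = 5 (Ctrl ZT0)
  expect_equal(out$fold[1], 1)          # dCt equal to reference
  expect_equal(out$fold[2], 0.5)        # ddCt = +1
  expect_equal(out$fold[3], 4)          # ddCt = -2
  expect_equal(out$fold[4], 2^(-(-0.5)))
  rec_bad <- rec; rec_bad$ct_housekeeping[2] <- NA
  expect_message(out2 <- delta_delta_ct(rec_bad), "dropping 1")
  expect_equal(nrow(out2), 3)
})

test_that("noiseless cosinor inputs are recovered exactly at any phase", {
  zts <- rep(c(0, 6, 12, 18), each = 3)
  for (acro in c(0, 3, 6, 11.7, 17.2, 23.5)) {
    y <- 5 + 2 * cos(2 * pi * (zts - acro) / 24)
    fit <- cosinor_fit(zts, y)
    expect_lt(abs(fit$baseline - 5), 1e-9)
    expect_lt(abs(fit$amplitude - 2), 1e-9)
    d <- abs(fit$acrophase - acro) %% 24
    expect_lt(min(d, 24 - d), 1e-9)
    expect_lt(fit$p_vs_flat, 1e-12)
    expect_equal(fit$selected_model, "cosine")
  }
  expect_error(cosinor_fit(c(0, 6, 12), c(1, 2, 3)), "underdetermined")
})

test_that("acrophase is equivariant under time shifts and amplitude non-negative", {
  zts <- rep(c(0, 6, 12, 18), each = 2)
  withr::with_seed(3, y <- 1 + 0.4 * cos(2 * pi * (zts - 4) / 24) +
                     rnorm(length(zts), 0, 0.05))
  f0 <- cosinor_fit(zts, y)
  for (shift in c(5, 13.25)) {
    # shifting the sampling clock by +s shifts the acrophase by +s (mod 24)
    fs <- cosinor_fit(zts + shift, y)
    d <- abs(fs$acrophase - (f0$acrophase + shift)) %% 24
    expect_lt(min(d, 24 - d), 1e-9)
  }
  expect_gte(f0$amplitude, 0)
})

test_that("model selection distinguishes cosine, linear and flat inputs", {
  zts <- rep(c(0, 6, 12, 18), each = 3)
  withr::with_seed(10, e <- rnorm(length(zts), 0, 0.05))
  strong <- cosinor_fit(zts, 2 + cos(2 * pi * (zts - 6) / 24) + e)
  expect_equal(select_model(strong), "cosine")
  # at the 4-ZT design a monotone trend aliases partly onto the cosine
  # basis, so the linear branch is exercised on the selection rule itself
  lin <- cosinor_fit(zts, 1 + 0.3 * zts + e)
  lin$p_vs_flat <- 0.4          # cosine not supported
  expect_equal(select_model(lin), "linear")
  lin$p_linear <- 0.5
  expect_equal(select_model(lin), "flat")
  # constant input: amplitude ~ 0, F ~ 0, not cosine
  flatf <- cosinor_fit(zts, 5 + e)
  expect_lt(flatf$amplitude, 0.1)
  expect_equal(select_model(flatf), "flat")
  # nested-model invariant
  expect_lte(strong$rss_cosine, strong$rss_flat + 1e-12)
})

test_that("K2 omnibus statistic matches an independent reference implementation", {
  # reference values computed with an external omnibus-normality oracle
  x1 <- c(1.2, -0.3, 0.5, 2.1, -1.7, 0.8, -0.9, 0.1, 1.5, -2.2, 0.4, -0.6,
          1.9, -1.1, 0.25, 0.75, -0.45, 1.05, -1.35, 0.65)
  r1 <- dagostino_k2(x1)
  expect_equal(r1$k2, 0.6113375917913626, tolerance = 1e-12)
  expect_equal(r1$p, 0.7366305541206806, tolerance = 1e-12)
  x2 <- c(0.05, 0.1, 0.2, 0.25, 0.3, 0.45, 0.5, 0.6, 0.8, 1.1, 1.6, 2.4,
          3.5, 5.2, 8.0)
  r2 <- dagostino_k2(x2)
  expect_equal(r2$k2, 14.351458321773944, tolerance = 1e-12)
  expect_equal(r2$p, 0.0007649277592979784, tolerance = 1e-12)
  expect_error(dagostino_k2(rep(1, 10)), "degenerate")
  expect_error(dagostino_k2(rnorm(5)), "n >= 8")
})

test_that("K2 rejects skewed residual distributions and passes normal ones", {
  withr::with_seed(12, {
    skew_rej <- mean(replicate(60, dagostino_k2(rexp(100))$p < 0.01))
    norm_rej <- mean(replicate(60, dagostino_k2(rnorm(100))$p < 0.05))
  })
  expect_gte(skew_rej, 0.95)
  expect_lte(norm_rej, 0.15)
})

test_that("residual normality is reported with a skip flag for short series", {
  zts <- c(0, 6, 12, 18)
  fit4 <- cosinor_fit(zts, c(1.2, 0.8, 1.1, 0.9))
  rn <- residual_normality(fit4)
  expect_true(rn$skipped)
  zts2 <- rep(zts, each = 3)
  withr::with_seed(2, fit12 <- cosinor_fit(zts2, rnorm(12, 5)))
  expect_false(residual_normality(fit12)$skipped)
})

test_that("per-ZT genotype tests apply Holm-Sidak within each gene", {
  base <- tidyr::crossing(gene = "Cry1", genotype = c("Ctrl", "cKO"),
                          zt = c(0, 6, 12, 18), rep = 1:6)
  base$value <- rep(c(1, 2, 3, 2.5, 1.5, 2), length.out = nrow(base))
  same <- per_zt_genotype_tests(base)
  expect_true(all(same$p_adj == 1))
  # one ZT shifted by ~5 sigma
  withr::with_seed(9, {
    shifted <- base
    shifted$value <- rnorm(nrow(shifted), 2, 0.2)
    shifted$value[shifted$genotype == "cKO" & shifted$zt == 12] <-
      shifted$value[shifted$genotype == "cKO" & shifted$zt == 12] + 1
  })
  r <- per_zt_genotype_tests(shifted)
  expect_lt(r$p_adj[r$zt == 12], 0.05)
  expect_true(all(r$p_adj[r$zt != 12] > 0.05))
  # correction is monotone: adjusted >= raw, ordering preserved
  expect_true(all(r$p_adj >= r$p))
  withr::with_seed(30, p <- runif(7))
  adj <- p_adjust_holm_sidak(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))
})

test_that("cosinor_by_gene carries tidy and glance outputs", {
  expr <- simulate_expression(n_per_zt = 4, seed = 3)
  fits <- cosinor_by_gene(expr |> dplyr::rename(value = "value"))
  expect_setequal(unique(fits$gene), c("Bmal1", "Cry1", "Dbp", "Per1"))
  expect_true(all(c("baseline", "amplitude", "acrophase",
                    "selected_model") %in% names(fits)))
  one <- fits$fit[[1]]
  expect_s3_class(one, "cosinor_fit")
  expect_equal(nrow(tidy(one)), 3)
  expect_equal(glance(one)$n, 16)
})
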