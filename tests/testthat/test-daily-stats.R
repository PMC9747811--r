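mk_psth <- function(rates) structure(
  list(bin_width = 0.01, rates = rates, n_trials = 20), class = "psth")

test_that("peak response respects the preferred half-cycle window", {
  zero <- mk_psth(rep(0, 200))
  expect_equal(peak_response(zero, "ON"), 0)
  off5 <- rep(0, 200); off5[121] <- 5   # phase 1.2-1.21
  expect_equal(peak_response(mk_psth(off5), "OFF"), 5)
  mixed <- rep(0, 200); mixed[11] <- 5; mixed[151] <- 8
  expect_equal(peak_response(mk_psth(mixed), "ON"), 5)
  expect_equal(peak_response(mk_psth(mixed), "OFF"), 8)
  expect_error(peak_response(zero, "ONOFF"), "restricted")
})

test_that("genotype KS tests match hand-checkable cases", {
  mk <- function(g, v) tibble::tibble(cluster = 1, zt = 0, ct = 100,
                                      genotype = g, peak_rate = v)
  same <- dplyr::bind_rows(mk("Ctrl", c(1, 2, 3)), mk("cKO", c(1, 2, 3)))
  r <- genotype_peak_test(same)
  expect_equal(r$D, 0)
  expect_equal(r$p, 1)
  # 10x shift with n = 50: overwhelming rejection
  withr::with_seed(3, v <- rlnorm(50))
  shift <- dplyr::bind_rows(mk("Ctrl", v), mk("cKO", 10 * v))
  expect_lt(genotype_peak_test(shift)$p, 1e-6)
  # n = 3 vs 3 equals the enumeration oracle
  x <- c(2.2, 5.1, 7.3); y <- c(3.0, 4.4, 9.1)
  got <- genotype_peak_test(dplyr::bind_rows(mk("Ctrl", x), mk("cKO", y)))
  ref <- brute_ks(x, y)
  expect_equal(got$D, ref$D)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
  # insufficient cells: stratum flagged, not an error
  tiny <- dplyr::bind_rows(mk("Ctrl", 1), mk("cKO", c(1, 2, 3)))
  expect_true(genotype_peak_test(tiny)$skipped)
})

test_that("ZT ANOVA with Tukey-Kramer flags only the shifted group", {
  withr::with_seed(17, {
    null_df <- tibble::tibble(zt = rep(c(0, 6, 12, 18), each = 30),
                              peak_rate = rnorm(120, 20, 4))
    shift_df <- null_df
    shift_df$peak_rate[shift_df$zt == 18] <-
      shift_df$peak_rate[shift_df$zt == 18] + 5 * 4
  })
  r0 <- zt_anova(null_df)
  expect_gt(r0$p, 0.01)
  r1 <- zt_anova(shift_df)
  expect_lt(r1$p, 1e-6)
  tuk <- r1$tukey
  vs18 <- grepl("18", tuk$comparison)
  expect_true(all(tuk$p_adj[vs18] < 0.01))
  expect_true(all(tuk$p_adj[!vs18] > 0.05))
  # groups with < 2 cells are dropped with a warning
  small <- dplyr::bind_rows(null_df, tibble::tibble(zt = 3, peak_rate = 1))
  expect_warning(zt_anova(small), "dropping")
})

test_that("normalized scatter divides by the per-ZT control maximum", {
  cm <- tidyr::crossing(zt = c(0, 18), ct = c(25, 50, 75, 100),
                        genotype = c("Ctrl", "cKO"))
  cm$mean_peak <- ifelse(cm$ct == 25, 10, ifelse(cm$ct == 50, 20,
                         ifelse(cm$ct == 75, 30, 40)))
  # cKO = 2x Ctrl at ZT18 only
  cm$mean_peak[cm$genotype == "cKO" & cm$zt == 18] <-
    2 * cm$mean_peak[cm$genotype == "cKO" & cm$zt == 18]
  out <- normalized_peak_scatter(cm)
  expect_equal(sort(out$norm_ctrl[out$zt == 0]), c(0.25, 0.5, 0.75, 1))
  expect_equal(out$norm_cko[out$zt == 0], out$norm_ctrl[out$zt == 0])
  expect_equal(out$norm_cko[out$zt == 18], 2 * out$norm_ctrl[out$zt == 18])
  expect_true(all(out$norm_ctrl <= 1))
  # day variant: one global control denominator
  cm2 <- cm
  cm2$mean_peak[cm2$zt == 0] <- cm2$mean_peak[cm2$zt == 0] / 2
  outd <- normalized_peak_scatter(cm2, variant = "day")
  expect_equal(max(outd$norm_ctrl), 1)
  expect_equal(max(outd$norm_ctrl[outd$zt == 0]), 0.5)
})

test_that("regime matching and maintenance percentages follow the label rules", {
  mes <- tibble::tibble(unit_id = sprintf("u%d", 1:6),
                        label = c("ON", "OFF", "ON", "ONOFF", "OFF", "ON"))
  pho <- tibble::tibble(unit_id = sprintf("u%d", 1:6),
                        label = c("ON", "ONOFF", NA, "ONOFF", "OFF", "OFF"))
  pairs <- match_units_across_regimes(mes, pho)
  expect_equal(pairs$category,
               c("maintained", "switched", "NA", "maintained", "maintained",
                 "switched"))
  pairs$genotype <- "Ctrl"
  mt <- polarity_maintenance(pairs)
  on_row <- mt[mt$class == "ON", ]
  expect_equal(on_row$n_maintained, 1)
  expect_equal(on_row$n_switched, 1)
  expect_equal(on_row$n_na, 1)
  expect_equal(on_row$pct_maintained, 50)
  expect_error(match_units_across_regimes(
    tibble::tibble(unit_id = "a", label = "ON"),
    tibble::tibble(unit_id = "b", label = "ON")), "shared")
})

test_that("maintenance percentage arithmetic covers the degenerate cases", {
  mk_pairs <- function(n_keep, n_switch) tibble::tibble(
    unit_id = as.character(seq_len(n_keep + n_switch)),
    genotype = "Ctrl", class = "OFF",
    category = rep(c("maintained", "switched"), c(n_keep, n_switch)))
  expect_equal(polarity_maintenance(mk_pairs(5, 0))$pct_maintained, 100)
  expect_equal(polarity_maintenance(mk_pairs(0, 7))$pct_maintained, 0)
  expect_equal(polarity_maintenance(mk_pairs(13, 7))$pct_maintained, 65)
})

test_that("Fisher maintenance test agrees with hypergeometric enumeration", {
  expect_equal(fisher_maintenance_test(c(10, 10), c(10, 10))$p, 1)
  # complete separation: closed form 2 / C(40, 20)
  r <- fisher_maintenance_test(c(20, 0), c(0, 20))
  expect_equal(r$p, 2 / choose(40, 20), tolerance = 1e-12)
  expect_warning(rd <- fisher_maintenance_test(c(0, 0), c(3, 4)),
                 "degenerate")
  expect_equal(rd$p, 1)
  # random tables with margins <= 30 against the enumeration oracle
  withr::with_seed(23, tabs <- matrix(sample(0:15, 4 * 40, TRUE), ncol = 4))
  for (i in seq_len(nrow(tabs))) {
    a <- tabs[i, 1]; b <- tabs[i, 2]; c <- tabs[i, 3]; d <- tabs[i, 4]
    if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) next
    expect_equal(fisher_maintenance_test(c(a, b), c(c, d))$p,
                 brute_fisher(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("peak record tables stratify by cluster, ZT and contrast", {
  prot <- quick_protocol(contrasts = c(50, 100), n_trials = 10)
  sess <- simulate_session(counts = c(ON = 8, OFF = 4), protocol = prot,
                           effects = null_effects(), seed = 77,
                           retina_id = "rA")
  truth <- session_truth(sess)
  calls <- tibble::tibble(unit_id = truth$unit_id,
                          label = truth$cell_class, retina_id = "rA")
  labels <- stats::setNames(rep(1L, nrow(truth)), truth$unit_id)
  pk <- peak_record_table(list(sess), calls, labels)
  expect_setequal(unique(pk$ct), c(50, 100))
  expect_equal(nrow(pk), 12 * 2)
  expect_true(all(pk$peak_rate >= 0))
  expect_true(all(pk$polarity %in% c("ON", "OFF")))
})
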