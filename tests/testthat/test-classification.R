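test_that("default templates place their mass in the expected half-cycles", {
  lib <- default_templates()
  at <- function(name, phase) unname(lib$curves[name, which(lib$grid == phase)])
  expect_equal(at("ON_sustained", 1.0), 1.0)
  expect_equal(at("OFF_sustained", 1.0), 0.0)
  expect_equal(at("ONOFF_symmetric", 1.0), 0.5)
  expect_equal(at("ON_delayed_sustained", 0.2), 0.0)
  # every template is a valid CDF
  expect_true(all(apply(lib$curves, 1, function(v) all(diff(v) >= -1e-12))))
  expect_equal(unname(lib$curves[, 200]), rep(1, 8))
})

test_that("template library JSON round-trips", {
  lib <- default_templates(theta = 0.3)
  f <- withr::local_tempfile(fileext = ".json")
  write_template_library(lib, f)
  lib2 <- read_template_library(f)
  expect_equal(lib2$theta, 0.3)
  expect_equal(lib2$info, lib$info)
  expect_equal(unname(lib2$curves), unname(lib$curves))
})

test_that("rate floor keeps units at or above 0.1 spikes/s on spontaneous gray", {
  p <- quick_protocol(spont_dur = 300)
  sess <- session_from_times(list(
    slow = seq(5, 300, length.out = 15),          # 0.05 sp/s
    edge = seq(0.5, 299.5, length.out = 30),      # exactly 0.1 sp/s
    fast = seq(0.01, 299.99, length.out = 600)    # 2 sp/s
  ), protocol = p)
  out <- rate_floor_filter(sess)
  expect_false(out$keep[out$unit_id == "slow"])
  expect_true(out$keep[out$unit_id == "edge"])
  expect_true(out$keep[out$unit_id == "fast"])
  expect_equal(out$spont_rate[out$unit_id == "edge"], 0.1)
})

test_that("responsiveness KS test matches a brute-force oracle on small samples", {
  # identical samples: D = 0, not kept
  r <- responsiveness_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(r$D, 0)
  expect_false(r$keep)
  # disjoint supports: D = 1, kept
  r2 <- responsiveness_test(seq(0.001, 0.05, length.out = 50),
                            seq(1, 2, length.out = 50))
  expect_equal(r2$D, 1)
  expect_true(r2$keep)
  # insufficient data is a reason code, not an exception
  r3 <- responsiveness_test(c(1), c(1, 2, 3))
  expect_false(r3$keep)
  expect_equal(r3$reason, "insufficient_isis")
  # n = m = 4 hand-listed samples against enumeration
  x <- c(0.11, 0.35, 0.52, 0.96); y <- c(0.20, 0.44, 0.61, 0.87)
  got <- responsiveness_test(x, y)
  ref <- brute_ks(x, y)
  expect_equal(got$D, ref$D)
  expect_equal(got$p, ref$p, tolerance = 1e-10)
})

test_that("template matching assigns by minimum sup-distance with strict-theta rejection", {
  lib <- default_templates()
  # a curve identical to a template matches it at distance zero
  for (nm in c("OFF_sustained", "ON_transient", "ONOFF_symmetric")) {
    call <- classify_polarity(lib$curves[nm, , drop = FALSE], lib)
    expect_equal(call$label, lib$info$class[lib$info$name == nm])
    expect_equal(call$best_template, nm)
    expect_equal(call$distance, 0)
  }
  # single-template library with a step template: the boundary distance is
  # exactly representable, so strict-theta rejection can be checked exactly
  step <- rep(c(0, 1), each = 100)
  one <- structure(list(
    info = tibble::tibble(name = "OFF_step", class = "OFF"),
    curves = matrix(step, 1, dimnames = list("OFF_step")),
    grid = lib$grid, theta = 0.25
  ), class = "template_library")
  at_theta <- rep(c(0.25, 1), each = 100)           # sup-distance exactly 0.25
  beyond <- rep(c(0.2501, 1), each = 100)
  expect_equal(classify_polarity(matrix(at_theta, 1), one)$label, "OFF")
  expect_true(is.na(classify_polarity(matrix(beyond, 1), one)$label))
})

test_that("uniform firing over the whole cycle is rejected as unclassifiable", {
  lib <- default_templates()
  diagonal <- matrix(lib$grid / 2, 1)
  # independent check of the minimum distance over all eight templates
  dmin <- min(apply(lib$curves, 1, function(tv) max(abs(tv - lib$grid / 2))))
  expect_gt(dmin, lib$theta)
  call <- classify_polarity(diagonal, lib)
  expect_true(is.na(call$label))
  expect_equal(call$distance, dmin)
})

test_that("fast black-onset bursts classify as OFF; an instantaneous spike pile does not", {
  lib <- default_templates()
  withr::with_seed(5, {
    burst <- 1.02 + rexp(400, 1 / 0.08)
    burst <- burst[burst < 2]
  })
  call <- classify_polarity(cumulative_cycle_distribution(burst), lib)
  expect_equal(call$label, "OFF")
  # all spikes in a single instant is not a physiological template shape
  pile <- classify_polarity(cumulative_cycle_distribution(rep(1.0, 100)), lib)
  expect_true(is.na(pile$label))
})

test_that("classification is exactly invariant to spike duplication", {
  withr::with_seed(6, ph <- c(runif(150, 0.02, 0.4), runif(30, 0, 2)))
  lib <- default_templates()
  c1 <- classify_polarity(cumulative_cycle_distribution(ph), lib)
  c2 <- classify_polarity(cumulative_cycle_distribution(rep(ph, 2)), lib)
  expect_identical(c1$label, c2$label)
  expect_identical(c1$distance, c2$distance)
})

test_that("classify_session applies rate floor, responsiveness and matching in order", {
  p <- quick_protocol(spont_dur = 300)
  on <- trial_onsets(p, 100)
  withr::with_seed(8, {
    resp_spikes <- sort(c(
      runif(60, 0, 300),                                 # spontaneous
      rep(on, each = 8) + rexp(8 * length(on), 1 / 0.08) # ON bursts
    ))
    silent_spont <- sort(runif(5, 0, 300))               # below rate floor
    unresp <- sort(runif(120, 0, protocol_duration(p)))  # flat through flashes
  })
  sess <- session_from_times(list(
    responder = resp_spikes, quiet = silent_spont, flat = unresp
  ), protocol = p)
  out <- classify_session(sess)
  expect_equal(out$filter[out$unit_id == "quiet"], "rate_floor")
  expect_true(out$filter[out$unit_id == "flat"] %in%
                c("unresponsive", "passed"))
  expect_equal(out$filter[out$unit_id == "responder"], "passed")
  expect_equal(out$label[out$unit_id == "responder"], "ON")
  expect_true(is.na(out$label[out$unit_id == "quiet"]))
})
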