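#' Default polarity template library
#'
#' Builds eight canonical cumulative-distribution templates from parametric
#' PSTH kernels on the standard 200-point cycle grid, covering sustained and
#' transient ON, OFF and ON-OFF response archetypes:
#'
#' * `ON_sustained`: uniform spiking over the white half `[0, 1)`.
#' * `ON_transient`: exponential burst (tau = 80 ms) at white onset.
#' * `OFF_sustained`: uniform over the black half `[1, 2)`.
#' * `OFF_transient`: exponential burst at black onset.
#' * `ONOFF_symmetric`: equal bursts at both onsets.
#' * `ONOFF_70_30` / `ONOFF_30_70`: asymmetric burst pairs.
#' * `ON_delayed_sustained`: uniform over `[0.2, 1)`.
#'
#' @param theta Rejection threshold on the sup-norm distance; a unit whose
#'   best-template distance exceeds `theta` (strictly) is labelled `NA`.
#' @param tau Burst decay constant for transient kernels (s).
#' @param latency Response onset lag after the luminance step (s); retinal
#'   output follows a flash with a short transduction delay, so every
#'   template kernel starts `latency` after its half-cycle onset.
#' @param grid_n Grid resolution.
#' @return A `template_library`: list with `info` (tibble `name`, `class`),
#'   `curves` (matrix, one row per template), `grid`, `theta`.
#' @export
default_templates <- function(theta = 0.25, tau = 0.08, latency = 0.02,
                              grid_n = 200) {
  grid <- seq_len(grid_n) * (2 / grid_n)
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  span <- 1 - latency
  burst_cdf <- function(x, onset) {
    # truncated exponential burst over [onset + latency, onset + 1)
    z <- pmin(pmax(x - onset - latency, 0), span)
    (1 - exp(-z / tau)) / (1 - exp(-span / tau))
  }
  on_cdf <- function(x) burst_cdf(x, 0)
  off_cdf <- function(x) burst_cdf(x, 1)
  curves <- rbind(
    ON_sustained         = clamp01((grid - latency) / span),
    ON_transient         = on_cdf(grid),
    ON_delayed_sustained = clamp01((grid - 0.2) / 0.8),
    OFF_sustained        = clamp01((grid - 1 - latency) / span),
    OFF_transient        = off_cdf(grid),
    ONOFF_symmetric      = 0.5 * on_cdf(grid) + 0.5 * off_cdf(grid),
    ONOFF_70_30          = 0.7 * on_cdf(grid) + 0.3 * off_cdf(grid),
    ONOFF_30_70          = 0.3 * on_cdf(grid) + 0.7 * off_cdf(grid)
  )
  info <- tibble::tibble(
    name = rownames(curves),
    class = c("ON", "ON", "ON", "OFF", "OFF", "ONOFF", "ONOFF", "ONOFF")
  )
  structure(
    list(info = info, curves = curves, grid = grid, theta = theta),
    class = "template_library"
  )
}

#' @export
print.template_library <- function(x, ...) {
  cat(sprintf("<template_library> %d templates (%s), theta = %.3g\n",
              nrow(x$info), paste(unique(x$info$class), collapse = "/"),
              x$theta))
  invisible(x)
}

#' Serialize a template library to JSON
#' @param library A `template_library`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_template_library <- function(library, path) {
  obj <- list(
    grid = library$grid,
    theta = library$theta,
    templates = purrr::pmap(
      list(library$info$name, library$info$class,
           seq_len(nrow(library$curves))),
      function(nm, cl, i) list(name = nm, class = cl,
                               values = unname(library$curves[i, ]))
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a template library from JSON
#' @param path File written by [write_template_library()].
#' @return A `template_library`.
#' @export
read_template_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  curves <- do.call(rbind, lapply(obj$templates$values, as.numeric))
  rownames(curves) <- obj$templates$name
  structure(
    list(
      info = tibble::tibble(name = obj$templates$name,
                            class = obj$templates$class),
      curves = curves,
      grid = as.numeric(obj$grid),
      theta = obj$theta
    ),
    class = "template_library"
  )
}

#' Filter units by spontaneous firing-rate floor
#'
#' Keeps units whose mean rate over the spontaneous gray segment is at least
#' `min_rate` (inclusive threshold).
#'
#' @param session An [rgc_session()].
#' @param min_rate Rate floor (spikes/s).
#' @return Tibble `unit_id`, `spont_rate`, `keep`.
#' @export
rate_floor_filter <- function(session, min_rate = 0.1) {
  stopifnot(inherits(session, "rgc_session"))
  ev <- session$protocol$events
  sp <- ev[ev$tag == "spont_gray", ]
  if (nrow(sp) == 0) stop("protocol has no spontaneous gray segment", call. = FALSE)
  w0 <- sp$onset[1]; w1 <- sp$onset[1] + sp$duration[1]
  all_units <- unique(session$spikes$unit_id)
  counts <- dplyr::count(
    dplyr::filter(session$spikes, .data$time >= w0, .data$time < w1),
    .data$unit_id
  )
  out <- tibble::tibble(unit_id = all_units)
  out <- dplyr::left_join(out, counts, by = "unit_id")
  out$n <- dplyr::coalesce(out$n, 0L)
  out$spont_rate <- out$n / (w1 - w0)
  out$keep <- out$spont_rate >= min_rate
  dplyr::select(out, "unit_id", "spont_rate", "keep")
}

#' Responsiveness test on inter-spike-interval distributions
#'
#' Two-sided two-sample Kolmogorov-Smirnov test between a unit's ISI sample
#' under static gray and under maximum-contrast flashes. Units whose ISI
#' distribution does not change under stimulation are considered
#' unresponsive.
#'
#' @param isi_gray,isi_flash Numeric ISI samples (s), at least 2 each.
#' @param alpha Significance level; the unit is kept when `p <= alpha`.
#' @return Tibble `keep`, `D`, `p`, `reason` (NA unless the test could not
#'   run, in which case `keep = FALSE` with reason `"insufficient_isis"`).
#' @export
responsiveness_test <- function(isi_gray, isi_flash, alpha = 0.05) {
  if (length(isi_gray) < 2 || length(isi_flash) < 2) {
    return(tibble::tibble(keep = FALSE, D = NA_real_, p = NA_real_,
                          reason = "insufficient_isis"))
  }
  kt <- suppressWarnings(
    stats::ks.test(isi_gray, isi_flash, alternative = "two.sided")
  )
  tibble::tibble(keep = kt$p.value <= alpha,
                 D = unname(kt$statistic), p = kt$p.value,
                 reason = NA_character_)
}

#' Classify unit polarity by greedy template matching
#'
#' Compares a unit's cumulative cycle distribution against every template in
#' the library under the sup-norm (default) or L2 distance and assigns the
#' class of the minimum-distance template; ties are broken by library order.
#' A unit whose best distance strictly exceeds the library threshold `theta`
#' is labelled `NA` (unknown).
#'
#' @param curve A `cycle_cdf`, or a list of them, or a numeric matrix with
#'   one curve per row on the library grid.
#' @param library A [default_templates()] library.
#' @param metric `"sup"` (Kolmogorov-style) or `"l2"` (root mean square).
#' @param unit_id Optional identifiers (recycled from names when absent).
#' @return Tibble `unit_id`, `label` (`ON`/`ONOFF`/`OFF`/`NA`),
#'   `best_template`, `distance`.
#' @export
classify_polarity <- function(curve, library = default_templates(),
                              metric = c("sup", "l2"), unit_id = NULL) {
  metric <- match.arg(metric)
  mat <- curves_to_matrix(curve, library$grid)
  if (is.null(unit_id)) {
    unit_id <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  }
  tl <- library$curves
  n <- nrow(mat)
  # distance of every unit (rows of mat) to every template (rows of tl)
  dmat <- matrix(NA_real_, n, nrow(tl))
  for (j in seq_len(nrow(tl))) {
    diffs <- abs(mat - matrix(tl[j, ], n, ncol(mat), byrow = TRUE))
    dmat[, j] <- if (metric == "sup") {
      diffs[cbind(seq_len(n), max.col(diffs, ties.method = "first"))]
    } else {
      sqrt(rowMeans(diffs^2))
    }
  }
  # ties broken by library order: first minimum wins
  jbest <- max.col(-dmat, ties.method = "first")
  dist <- dmat[cbind(seq_len(n), jbest)]
  best <- library$info$name[jbest]
  labs <- ifelse(dist > library$theta, NA_character_,
                 library$info$class[jbest])
  tibble::tibble(unit_id = unit_id, label = labs,
                 best_template = best, distance = dist)
}

# Coerce curve input (cycle_cdf, list of them, or matrix) onto a common grid.
curves_to_matrix <- function(curve, grid) {
  if (inherits(curve, "cycle_cdf")) curve <- list(curve)
  if (is.list(curve) && !is.data.frame(curve)) {
    rows <- lapply(curve, function(cc) {
      stopifnot(inherits(cc, "cycle_cdf"))
      if (length(cc$grid) == length(grid) && all(abs(cc$grid - grid) < 1e-12)) {
        cc$values
      } else {
        stats::approx(cc$grid, cc$values, xout = grid, rule = 2,
                      method = "linear", ties = "ordered")$y
      }
    })
    mat <- do.call(rbind, rows)
    if (!is.null(names(curve))) rownames(mat) <- names(curve)
    mat
  } else {
    mat <- as.matrix(curve)
    stopifnot(ncol(mat) == length(grid))
    mat
  }
}

#' Classify all responsive units of a session
#'
#' Full per-session classification path: spontaneous rate floor, ISI
#' responsiveness test (gray vs. maximum-contrast flashes), then template
#' matching on the CT100 cumulative cycle distribution. The filters are
#' applied in this order; units failing either filter are reported with the
#' failure reason and label `NA`.
#'
#' @param session An [rgc_session()].
#' @param library Template library.
#' @param min_rate Spontaneous rate floor (spikes/s).
#' @param alpha Responsiveness test level.
#' @param ct Contrast block used for polarity (default the CT100 block).
#' @return Tibble `unit_id`, `label`, `best_template`, `distance`,
#'   `spont_rate`, `responsive_p`, `filter` (`"passed"`, `"rate_floor"`,
#'   `"unresponsive"`, `"insufficient_isis"`, `"no_spikes"`).
#' @export
classify_session <- function(session, library = default_templates(),
                             min_rate = 0.1, alpha = 0.05, ct = 100) {
  stopifnot(inherits(session, "rgc_session"))
  floor_tbl <- rate_floor_filter(session, min_rate)
  ev <- session$protocol$events
  sp <- ev[ev$tag == "spont_gray", ]
  gray_win <- c(sp$onset[1], sp$onset[1] + sp$duration[1])
  onsets <- trial_onsets(session$protocol, ct)
  flash_win <- c(onsets[1], onsets[length(onsets)] + 2 * session$protocol$flash_dur)
  units <- split(session$spikes$time, session$spikes$unit_id)

  rows <- purrr::map(floor_tbl$unit_id, function(uid) {
    tt <- units[[as.character(uid)]] %||% numeric(0)
    srate <- floor_tbl$spont_rate[floor_tbl$unit_id == uid]
    base <- tibble::tibble(
      unit_id = uid, label = NA_character_, best_template = NA_character_,
      distance = NA_real_, spont_rate = srate, responsive_p = NA_real_
    )
    if (!floor_tbl$keep[floor_tbl$unit_id == uid]) {
      base$filter <- "rate_floor"
      return(base)
    }
    gi <- tt[tt >= gray_win[1] & tt < gray_win[2]]
    fi <- tt[tt >= flash_win[1] & tt < flash_win[2]]
    if (length(gi) < 3 || length(fi) < 3) {
      base$filter <- "insufficient_isis"
      return(base)
    }
    rt <- responsiveness_test(diff(gi), diff(fi), alpha)
    base$responsive_p <- rt$p
    if (!rt$keep) {
      base$filter <- "unresponsive"
      return(base)
    }
    ph <- epoch_spikes(tt, session$protocol, ct)
    if (nrow(ph) == 0) {
      base$filter <- "no_spikes"
      return(base)
    }
    cc <- cumulative_cycle_distribution(ph)
    call <- classify_polarity(cc, library, unit_id = as.character(uid))
    base$label <- call$label
    base$best_template <- call$best_template
    base$distance <- call$distance
    base$filter <- "passed"
    base
  })
  dplyr::bind_rows(rows)
}
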