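#' Recording session container
#'
#' Bundles the sorted spike trains of one retina with its stimulation
#' protocol and experimental metadata (genotype, Zeitgeber time, luminance
#' regime).
#'
#' @param spikes Tibble/data frame with columns `unit_id`, `time` (s). Spike
#'   times must be non-negative, within the protocol duration, and strictly
#'   increasing within each unit.
#' @param protocol A [build_flash_protocol()] object.
#' @param genotype `"Ctrl"` or `"cKO"`.
#' @param zt Zeitgeber time, one of 0, 6, 12, 18 (h).
#' @param regime `"mesopic"` or `"photopic"`; must match the protocol.
#' @param retina_id Identifier of the retina/dataset.
#' @return An `rgc_session` object (list with the fields above, `spikes`
#'   stored as a tibble sorted by unit and time).
#' @export
rgc_session <- function(spikes, protocol, genotype = c("Ctrl", "cKO"),
                        zt = 0, regime = protocol$regime,
                        retina_id = "retina1") {
  genotype <- match.arg(genotype)
  stopifnot(inherits(protocol, "flash_protocol"))
  if (!zt %in% c(0, 6, 12, 18)) {
    stop("zt must be one of 0, 6, 12, 18", call. = FALSE)
  }
  spikes <- tibble::as_tibble(spikes)
  stopifnot(all(c("unit_id", "time") %in% names(spikes)))
  if (nrow(spikes) > 0) {
    if (any(spikes$time < 0) || any(spikes$time > protocol_duration(protocol))) {
      stop("spike times must lie within the protocol duration", call. = FALSE)
    }
  }
  spikes <- dplyr::arrange(spikes, .data$unit_id, .data$time)
  dup <- dplyr::group_by(spikes, .data$unit_id)
  dup <- dplyr::summarise(dup, bad = anyDuplicated(.data$time) > 0)
  if (any(dup$bad)) {
    stop("duplicate spike times within a unit are not allowed", call. = FALSE)
  }
  structure(
    list(
      genotype = genotype, zt = zt, regime = regime,
      retina_id = retina_id, protocol = protocol, spikes = spikes
    ),
    class = "rgc_session"
  )
}

#' @export
print.rgc_session <- function(x, ...) {
  cat(sprintf(
    "<rgc_session> %s, ZT%d, %s regime, %d units, %d spikes (%s)\n",
    x$genotype, as.integer(x$zt), x$regime,
    dplyr::n_distinct(x$spikes$unit_id), nrow(x$spikes), x$retina_id
  ))
  invisible(x)
}

#' Epoch spike times into flash-cycle phases
#'
#' Aligns spikes to the white-flash triggers of one contrast block and
#' re-expresses them as phases in `[0, 2)` s of the 2 s white/black cycle
#' (phase 0 = white onset, `[0, 1)` white half, `[1, 2)` black half).
#'
#' @param times Numeric spike times (s), session clock.
#' @param protocol A `flash_protocol`.
#' @param ct Contrast of the block to epoch against.
#' @return Tibble with columns `trial` (1..n_trials) and `phase` (s in
#'   `[0, 2)`). Spikes outside the block's flash cycles are dropped. The trial
#'   onsets used are attached as attribute `onsets` so that
#'   `phase + onsets[trial]` recovers the original times exactly.
#' @export
epoch_spikes <- function(times, protocol, ct) {
  onsets <- trial_onsets(protocol, ct)
  cycle <- 2 * protocol$flash_dur
  idx <- findInterval(times, onsets)
  keep <- idx >= 1L & times < onsets[length(onsets)] + cycle &
    (times - onsets[pmax(idx, 1L)]) < cycle
  out <- tibble::tibble(
    trial = idx[keep],
    phase = times[keep] - onsets[idx[keep]]
  )
  attr(out, "onsets") <- onsets
  attr(out, "n_trials") <- length(onsets)
  out
}

#' Peristimulus time histogram over the flash cycle
#'
#' Bins pooled spike phases from all trials into fixed-width bins and
#' converts counts to firing rates: `rate[b] = count[b] / (n_trials *
#' bin_width)`.
#'
#' @param phases Tibble from [epoch_spikes()] (columns `trial`, `phase`), or a
#'   numeric vector of phases.
#' @param n_trials Number of trials pooled; taken from the `epoch_spikes()`
#'   attribute when present.
#' @param bin_width Bin width (s); must divide the 2 s cycle exactly.
#' @param cycle Cycle duration (s).
#' @return A `psth` object: list with `bin_width`, `rates` (spikes/s, one per
#'   bin), `n_trials`. Bin `b` covers `[(b-1) * bin_width, b * bin_width)`.
#' @export
psth <- function(phases, n_trials = NULL, bin_width = 0.01, cycle = 2) {
  if (is.data.frame(phases)) {
    if (is.null(n_trials)) n_trials <- attr(phases, "n_trials")
    phases <- phases$phase
  }
  if (is.null(n_trials)) {
    stop("n_trials must be supplied when phases is a bare vector", call. = FALSE)
  }
  n_bins <- cycle / bin_width
  if (abs(n_bins - round(n_bins)) > 1e-9) {
    stop("bin_width must divide the cycle exactly", call. = FALSE)
  }
  n_bins <- as.integer(round(n_bins))
  counts <- tabulate(pmin(floor(phases / bin_width) + 1L, n_bins), nbins = n_bins)
  structure(
    list(
      bin_width = bin_width,
      rates = counts / (n_trials * bin_width),
      n_trials = as.integer(n_trials)
    ),
    class = "psth"
  )
}

#' @export
print.psth <- function(x, ...) {
  cat(sprintf("<psth> %d bins of %.0f ms, %d trials, peak %.2f spikes/s\n",
              length(x$rates), 1000 * x$bin_width, x$n_trials, max(x$rates)))
  invisible(x)
}

#' @method as_tibble psth
#' @export
as_tibble.psth <- function(x, ...) {
  tibble::tibble(
    phase = (seq_along(x$rates) - 0.5) * x$bin_width,
    rate = x$rates
  )
}

#' Normalized cumulative distribution of spike phases over the cycle
#'
#' Pools spike phases across trials and evaluates their empirical CDF on a
#' fixed phase grid. Normalizing by total spike count makes units with very
#' different firing rates directly comparable: the curve encodes only *when*
#' in the cycle a cell fires, not how much.
#'
#' @param phases Tibble from [epoch_spikes()] or numeric phases in `[0, 2)`.
#' @param grid_n Number of grid points (default 200, i.e. the 10 ms PSTH
#'   resolution); the grid is the right bin edges `(1:grid_n) * cycle/grid_n`.
#' @param cycle Cycle duration (s).
#' @return A `cycle_cdf` object: list with `grid`, `values` (non-decreasing,
#'   final value 1) and `n_spikes`.
#' @export
cumulative_cycle_distribution <- function(phases, grid_n = 200, cycle = 2) {
  if (is.data.frame(phases)) phases <- phases$phase
  if (length(phases) < 1) {
    stop("cumulative distribution undefined with zero spikes; filter first",
         call. = FALSE)
  }
  grid <- seq_len(grid_n) * (cycle / grid_n)
  values <- stats::ecdf(phases)(grid)
  structure(
    list(grid = grid, values = values, n_spikes = length(phases)),
    class = "cycle_cdf"
  )
}

#' @export
print.cycle_cdf <- function(x, ...) {
  cat(sprintf("<cycle_cdf> %d grid points, %d spikes, F(1s) = %.3f\n",
              length(x$grid), x$n_spikes, x$values[which.min(abs(x$grid - 1))]))
  invisible(x)
}

# Fast path: empirical CDF values on the standard grid for many phase sets
# at once (rows of the result match the list order). Matches
# cumulative_cycle_distribution() evaluated at the right bin edges.
cdf_matrix <- function(phase_list, grid_n = 200, cycle = 2) {
  bw <- cycle / grid_n
  t(vapply(phase_list, function(p) {
    cumsum(tabulate(pmax(ceiling(p / bw), 1), nbins = grid_n)) / length(p)
  }, numeric(grid_n)))
}

#' Inter-spike intervals within a time window
#'
#' @param times Sorted spike times (s).
#' @param window Length-2 numeric `c(start, end)`; half-open `[start, end)`.
#' @return Numeric vector of successive differences (> 0) of in-window
#'   spikes, or an error when fewer than 2 spikes fall in the window.
#' @export
isi_sample <- function(times, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  w <- times[times >= window[1] & times < window[2]]
  if (length(w) < 2) {
    stop("need at least 2 spikes in the window for ISIs", call. = FALSE)
  }
  diff(w)
}

#' Mean firing rate
#' @param times Spike times within the segment.
#' @param duration Segment duration (s), > 0.
#' @return Spikes per second.
#' @export
mean_rate <- function(times, duration) {
  stopifnot(duration > 0)
  length(times) / duration
}

#' Per-unit cycle features for one contrast block
#'
#' Convenience wrapper: epochs every unit of a session at the given contrast
#' and returns PSTHs and cumulative distributions for units with at least one
#' in-block spike.
#'
#' @param session An [rgc_session()].
#' @param ct Contrast block to use (default 100, the maximum-contrast block
#'   used for classification and clustering).
#' @param bin_width PSTH bin width (s).
#' @return Tibble with columns `unit_id`, `n_spikes`, and list-columns
#'   `psth` and `cdf`.
#' @export
unit_cycle_features <- function(session, ct = 100, bin_width = 0.01) {
  stopifnot(inherits(session, "rgc_session"))
  units <- split(session$spikes$time, session$spikes$unit_id)
  rows <- purrr::imap(units, function(tt, uid) {
    ph <- epoch_spikes(tt, session$protocol, ct)
    if (nrow(ph) == 0) return(NULL)
    tibble::tibble(
      unit_id = uid,
      n_spikes = nrow(ph),
      psth = list(psth(ph, bin_width = bin_width)),
      cdf = list(cumulative_cycle_distribution(ph))
    )
  })
  dplyr::bind_rows(purrr::compact(rows))
}

#' Read a spike table from delimited text
#'
#' Expects columns `unit_id` and either `time` or `spike_time_s`.
#'
#' @param path CSV or TSV file.
#' @return Tibble with columns `unit_id`, `time`.
#' @export
read_spike_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  if ("spike_time_s" %in% names(x) && !"time" %in% names(x)) {
    x <- dplyr::rename(x, time = "spike_time_s")
  }
  stopifnot(all(c("unit_id", "time") %in% names(x)))
  dplyr::arrange(x[, c("unit_id", "time")], .data$unit_id, .data$time)
}

#' Plot a PSTH
#' @param object A `psth`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psth
#' @export
autoplot.psth <- function(object, ...) {
  df <- as_tibble.psth(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$rate)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "cycle phase (s; white 0-1, black 1-2)",
                  y = "firing rate (spikes/s)")
}

#' Plot a cumulative cycle distribution
#' @param object A `cycle_cdf`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cycle_cdf
#' @export
autoplot.cycle_cdf <- function(object, ...) {
  df <- tibble::tibble(phase = object$grid, value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "cycle phase (s)", y = "cumulative spike fraction")
}
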