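#' Michelson contrast between two luminances
#'
#' Computes the Michelson contrast `100 * (l_max - l_min) / (l_max + l_min)`
#' between the brightest and darkest luminance of a full-field flash pair,
#' on the 0-100 scale used to label stimulus blocks (CT25, CT50, ...).
#'
#' @param l_max Brightest luminance (linear units, e.g. cd/m^2). Vectorised.
#' @param l_min Darkest luminance, same units. Vectorised.
#' @return Numeric vector of contrasts in `[0, 100]`.
#' @examples
#' michelson_contrast(1, 0)        # 100
#' michelson_contrast(0.75, 0.25)  # 50
#' @export
michelson_contrast <- function(l_max, l_min) {
  stopifnot(is.numeric(l_max), is.numeric(l_min))
  if (any(l_min < 0) || any(l_max < l_min)) {
    stop("require l_max >= l_min >= 0", call. = FALSE)
  }
  if (any(l_max + l_min == 0)) {
    stop("contrast undefined when both luminances are zero", call. = FALSE)
  }
  100 * (l_max - l_min) / (l_max + l_min)
}

#' Luminance pair realizing a given contrast around a mean gray
#'
#' Inverts the Michelson formula: for an isoluminant gray `g` and contrast
#' `ct`, the symmetric flash pair is `(g (1 + ct/100), g (1 - ct/100))`,
#' whose mean is `g` and whose Michelson contrast is `ct`.
#'
#' @param mean_gray Mean (isoluminant gray) luminance, > 0.
#' @param ct Contrast in `[0, 100]`. Vectorised.
#' @return A tibble with columns `ct`, `l_max`, `l_min`.
#' @export
contrast_pair <- function(mean_gray, ct) {
  stopifnot(is.numeric(mean_gray), length(mean_gray) == 1, mean_gray > 0)
  if (any(ct < 0 | ct > 100)) {
    stop("contrast must lie in [0, 100]", call. = FALSE)
  }
  tibble::tibble(
    ct = as.numeric(ct),
    l_max = mean_gray * (1 + ct / 100),
    l_min = mean_gray * (1 - ct / 100)
  )
}

#' Build the full-field flash stimulation protocol
#'
#' Assembles the event schedule used throughout the pipeline: an initial
#' spontaneous mean-gray segment, then one block per contrast consisting of a
#' gray baseline followed by `n_trials` alternating 1 s white / 1 s black
#' full-field flashes symmetric around the mean gray. The baseline gray of
#' each block doubles as the inter-block gray at `mean_gray`.
#'
#' @param regime `"mesopic"` or `"photopic"`; metadata only, contrast
#'   arithmetic is regime independent.
#' @param mean_gray Mean gray luminance (linear units). Defaults to the
#'   regime's luminance (0.092 mesopic, 9.20 photopic cd/m^2).
#' @param contrasts Michelson contrasts of the flash blocks, presented in the
#'   given order (default ascending 25, 50, 75, 100).
#' @param n_trials White/black flash pairs per contrast block.
#' @param flash_dur Duration of each flash half (s).
#' @param spont_dur Duration of the initial spontaneous gray segment (s).
#' @param baseline_dur Gray baseline before each contrast block (s).
#' @return A `flash_protocol` object: list with fields `regime`, `mean_gray`,
#'   `contrasts`, `n_trials`, `flash_dur` and `events`, a tibble with columns
#'   `onset`, `duration`, `luminance`, `tag`, `ct`, `trial`. Events are
#'   contiguous, non-overlapping, half-open `[onset, onset + duration)`.
#' @export
build_flash_protocol <- function(regime = c("mesopic", "photopic"),
                                 mean_gray = NULL,
                                 contrasts = c(25, 50, 75, 100),
                                 n_trials = 20,
                                 flash_dur = 1,
                                 spont_dur = 300,
                                 baseline_dur = 60) {
  regime <- match.arg(regime)
  if (is.null(mean_gray)) {
    mean_gray <- if (regime == "mesopic") 0.092 else 9.20
  }
  if (length(contrasts) == 0) {
    stop("at least one contrast is required", call. = FALSE)
  }
  stopifnot(flash_dur > 0, spont_dur > 0, baseline_dur > 0, n_trials >= 1)
  if (any(contrasts < 0 | contrasts > 100)) {
    stop("contrast must lie in [0, 100]", call. = FALSE)
  }

  rows <- list(tibble::tibble(
    duration = spont_dur, luminance = mean_gray,
    tag = "spont_gray", ct = NA_real_, trial = NA_integer_
  ))
  for (ct in contrasts) {
    pair <- contrast_pair(mean_gray, ct)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      duration = baseline_dur, luminance = mean_gray,
      tag = "baseline_gray", ct = ct, trial = NA_integer_
    )
    rows[[length(rows) + 1L]] <- tibble::tibble(
      duration = flash_dur,
      luminance = rep(c(pair$l_max, pair$l_min), n_trials),
      tag = rep(c("flash_white", "flash_black"), n_trials),
      ct = ct,
      trial = rep(seq_len(n_trials), each = 2L)
    )
  }
  events <- dplyr::bind_rows(rows)
  events <- dplyr::mutate(events,
    onset = cumsum(c(0, utils::head(.data$duration, -1)))
  )
  events <- dplyr::select(events, "onset", "duration", "luminance",
                          "tag", "ct", "trial")

  structure(
    list(
      regime = regime,
      mean_gray = mean_gray,
      contrasts = as.numeric(contrasts),
      n_trials = as.integer(n_trials),
      flash_dur = flash_dur,
      events = events
    ),
    class = "flash_protocol"
  )
}

#' @export
print.flash_protocol <- function(x, ...) {
  cat(sprintf(
    "<flash_protocol> %s regime, mean gray %.4g, %d contrast block(s) [%s], %d trials each, %.0f s total\n",
    x$regime, x$mean_gray, length(x$contrasts),
    paste(x$contrasts, collapse = ", "), x$n_trials, protocol_duration(x)
  ))
  invisible(x)
}

#' Total protocol duration in seconds
#' @param protocol A `flash_protocol`.
#' @return Duration (s), equal to the sum of event durations.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "flash_protocol"))
  sum(protocol$events$duration)
}

#' Flash (white-onset) trigger times for one contrast block
#'
#' Onset of each white flash defines phase 0 of the corresponding 2 s
#' white/black cycle.
#'
#' @param protocol A `flash_protocol`.
#' @param ct Contrast of the block.
#' @return Numeric vector of `n_trials` white-flash onsets (s).
#' @export
trial_onsets <- function(protocol, ct) {
  stopifnot(inherits(protocol, "flash_protocol"))
  if (!ct %in% protocol$contrasts) {
    stop(sprintf("protocol has no block at CT%s", format(ct)), call. = FALSE)
  }
  ev <- protocol$events
  ev$onset[ev$tag == "flash_white" & ev$ct == ct]
}

#' Serialize a protocol to JSON
#'
#' @param protocol A `flash_protocol`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  stopifnot(inherits(protocol, "flash_protocol"))
  obj <- list(
    regime = protocol$regime,
    mean_gray = protocol$mean_gray,
    contrasts = protocol$contrasts,
    n_trials = protocol$n_trials,
    flash_dur = protocol$flash_dur,
    events = protocol$events
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a protocol back from JSON
#' @param path JSON file written by [write_protocol_json()].
#' @return A `flash_protocol`.
#' @export
read_protocol_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- tibble::as_tibble(obj$events)
  ev$ct <- as.numeric(ev$ct)
  ev$trial <- as.integer(ev$trial)
  structure(
    list(
      regime = obj$regime,
      mean_gray = obj$mean_gray,
      contrasts = as.numeric(obj$contrasts),
      n_trials = as.integer(obj$n_trials),
      flash_dur = obj$flash_dur,
      events = ev
    ),
    class = "flash_protocol"
  )
}

#' Export flash trigger times as a one-column text file
#'
#' Writes the white-flash onsets of every contrast block (in protocol order),
#' one time per line, for alignment checks against external acquisition logs.
#'
#' @param protocol A `flash_protocol`.
#' @param path Output text file.
#' @return `path`, invisibly.
#' @export
write_trigger_times <- function(protocol, path) {
  stopifnot(inherits(protocol, "flash_protocol"))
  on <- unlist(lapply(protocol$contrasts, function(ct) trial_onsets(protocol, ct)))
  writeLines(format(on, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}
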