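#' Default RGC kinetic models
#'
#' Parametric firing-rate kernels used by [simulate_session()]. Each row is
#' one response archetype: `rate(t) = baseline_rate + gain_factor *
#' peak_gain * kernel(phase) * cr(CT)` where `kernel` is 1 over the
#' preferred half-cycle for sustained types, an exponential burst (decay
#' `decay_tau`) for transient types, and `cr(CT) = CT / (CT + semisat)` is a
#' Naka-Rushton contrast-response factor.
#'
#' @param semisat Contrast semisaturation (CT units, default 30).
#' @return Tibble `cell_class`, `subtype`, `baseline_rate` (spikes/s),
#'   `peak_gain` (spikes/s), `decay_tau` (s, NA for sustained), `latency`
#'   (s), `semisat`, `weight` (mixing proportion within the class).
#' @export
default_kinetic_models <- function(semisat = 30) {
  tibble::tibble(
    cell_class = c("ON", "ON", "OFF", "OFF", "ONOFF"),
    subtype = c("ON_sust", "ON_trans", "OFF_sust", "OFF_trans", "ONOFF_trans"),
    baseline_rate = c(1, 1, 1, 1, 1),
    peak_gain = c(60, 120, 60, 120, 120),
    decay_tau = c(NA, 0.08, NA, 0.08, 0.08),
    latency = c(0.02, 0.02, 0.02, 0.02, 0.02),
    semisat = semisat,
    weight = c(0.5, 0.5, 0.5, 0.5, 1)
  )
}

#' Four well-separated ON kinetic models
#'
#' A purely-ON model set with four distinct kernels (sustained, fast
#' transient, slow transient, delayed sustained), used for clustering
#' parameter-recovery checks.
#'
#' @param semisat Contrast semisaturation.
#' @return Kinetic model tibble as in [default_kinetic_models()].
#' @export
on_four_kernel_models <- function(semisat = 30) {
  tibble::tibble(
    cell_class = "ON",
    subtype = c("ON_sust", "ON_trans_fast", "ON_trans_slow", "ON_delayed"),
    baseline_rate = 1,
    peak_gain = c(80, 200, 120, 80),
    decay_tau = c(NA, 0.04, 0.15, NA),
    latency = c(0.02, 0.02, 0.10, 0.45),
    semisat = semisat,
    weight = 0.25
  )
}

#' Multiplicative peak-gain effect table
#'
#' Ground-truth genotype-by-ZT gain factors injected by the generator.
#' The default encodes the qualitative study conditions: control responses
#' elevated at ZT0 and ZT12, and a x1.5 knockout gain at ZT18.
#'
#' @param ctrl_zt0 .. cko_zt18 Gain factors per (genotype, ZT) cell.
#' @return Tibble `genotype`, `zt`, `gain_factor`.
#' @export
effect_table <- function(ctrl_zt0 = 1, ctrl_zt6 = 1, ctrl_zt12 = 1,
                         ctrl_zt18 = 1, cko_zt0 = 1, cko_zt6 = 1,
                         cko_zt12 = 1, cko_zt18 = 1) {
  tb <- tibble::tibble(
    genotype = rep(c("Ctrl", "cKO"), each = 4),
    zt = rep(c(0, 6, 12, 18), 2),
    gain_factor = c(ctrl_zt0, ctrl_zt6, ctrl_zt12, ctrl_zt18,
                    cko_zt0, cko_zt6, cko_zt12, cko_zt18)
  )
  if (any(tb$gain_factor <= 0)) stop("gain factors must be > 0", call. = FALSE)
  tb
}

#' @rdname effect_table
#' @export
default_effects <- function() {
  effect_table(ctrl_zt0 = 1.2, ctrl_zt12 = 1.2, cko_zt18 = 1.5)
}

#' @rdname effect_table
#' @export
null_effects <- function() effect_table()

# Kernel value at cycle phases for one model row (vectorised over phase).
kernel_value <- function(phase, model) {
  on_part <- function(p, lat, tau) {
    act <- p >= lat & p < 1
    if (is.na(tau)) as.numeric(act)
    else as.numeric(act) * exp(-(pmax(p - lat, 0)) / tau)
  }
  cls <- model$cell_class
  if (cls == "ON") {
    on_part(phase, model$latency, model$decay_tau)
  } else if (cls == "OFF") {
    on_part(phase - 1, model$latency, model$decay_tau)
  } else {
    0.5 * on_part(phase, model$latency, model$decay_tau) +
      0.5 * on_part(phase - 1, model$latency, model$decay_tau)
  }
}

# Homogeneous Poisson spikes on [t0, t1) at rate r.
hpp <- function(t0, t1, r) {
  n <- stats::rpois(1, r * (t1 - t0))
  if (n == 0) return(numeric(0))
  sort(stats::runif(n, t0, t1))
}

#' Simulate one HD-MEA recording session
#'
#' Draws, per unit, spikes from an inhomogeneous Poisson process over the
#' full protocol: spontaneous and gray segments at the unit's baseline
#' rate, flash cycles at `baseline + gain_factor(genotype, zt) * peak_gain *
#' kernel(phase) * CT/(CT + semisat)` via thinning. Deterministic given the
#' seed. Ground-truth classes are attached as attribute `truth`.
#'
#' @param counts Named integer vector of unit counts per class, e.g.
#'   `c(ON = 50, OFF = 20, ONOFF = 40)` (the reduced per-retina cohort;
#'   recordings average roughly 241 ON / 97 OFF / 194 ON-OFF units).
#' @param protocol A [build_flash_protocol()]; its regime is the session's.
#' @param genotype,zt Session metadata; select the gain factor from
#'   `effects`.
#' @param models Kinetic model tibble ([default_kinetic_models()]).
#' @param effects Effect table ([default_effects()]).
#' @param retina_id Session identifier.
#' @param seed Integer seed.
#' @param refractory Absolute refractory period (s); 0 disables (default).
#'   A small value (e.g. 0.0015) gives ISI realism when wanted.
#' @return An [rgc_session()] with attribute `truth`: tibble `unit_id`,
#'   `cell_class`, `subtype`.
#' @export
simulate_session <- function(counts = c(ON = 50, OFF = 20, ONOFF = 40),
                             protocol = build_flash_protocol("mesopic"),
                             genotype = "Ctrl", zt = 0,
                             models = default_kinetic_models(),
                             effects = default_effects(),
                             retina_id = "sim1", seed = 1,
                             refractory = 0) {
  stopifnot(all(counts >= 0), any(counts > 0))
  eff <- effects$gain_factor[effects$genotype == genotype & effects$zt == zt]
  if (length(eff) != 1) stop("effects table lacks (genotype, zt) entry", call. = FALSE)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 0))

  ev <- protocol$events
  gray_ev <- ev[ev$tag %in% c("spont_gray", "baseline_gray"), ]
  flash_blocks <- lapply(protocol$contrasts, function(ct) {
    on <- trial_onsets(protocol, ct)
    list(ct = ct, start = on[1],
         end = on[length(on)] + 2 * protocol$flash_dur, onsets = on)
  })

  # unit table with classes and subtypes
  unit_rows <- purrr::map_dfr(names(counts), function(cls) {
    n <- counts[[cls]]
    if (n == 0) return(NULL)
    sub <- models[models$cell_class == cls, ]
    if (nrow(sub) == 0) stop("no kinetic model for class ", cls, call. = FALSE)
    pick <- sample.int(nrow(sub), n, replace = TRUE, prob = sub$weight)
    tibble::tibble(cell_class = cls, model_idx = which(models$cell_class == cls)[pick])
  })
  n_units <- nrow(unit_rows)
  unit_rows$unit_id <- sprintf("%s_u%03d", retina_id, seq_len(n_units))
  unit_rows$subtype <- models$subtype[unit_rows$model_idx]

  spike_list <- vector("list", n_units)
  for (i in seq_len(n_units)) {
    mod <- models[unit_rows$model_idx[i], ]
    base <- mod$baseline_rate
    tt <- unlist(lapply(seq_len(nrow(gray_ev)), function(j) {
      hpp(gray_ev$onset[j], gray_ev$onset[j] + gray_ev$duration[j], base)
    }))
    for (blk in flash_blocks) {
      cr <- blk$ct / (blk$ct + mod$semisat)
      gain <- eff * mod$peak_gain * cr
      rmax <- base + gain
      cand <- hpp(blk$start, blk$end, rmax)
      if (length(cand) > 0) {
        tr <- findInterval(cand, blk$onsets)
        phase <- cand - blk$onsets[tr]
        rate <- base + gain * kernel_value(phase, mod)
        keep <- stats::runif(length(cand)) < rate / rmax
        tt <- c(tt, cand[keep])
      }
    }
    # uniform draws have finite granularity, so exact collisions can occur;
    # spike trains are strictly increasing by contract
    tt <- unique(sort(tt))
    if (refractory > 0 && length(tt) > 1) {
      keep <- logical(length(tt)); keep[1] <- TRUE; last <- tt[1]
      for (j in 2:length(tt)) {
        if (tt[j] - last >= refractory) { keep[j] <- TRUE; last <- tt[j] }
      }
      tt <- tt[keep]
    }
    spike_list[[i]] <- tibble::tibble(unit_id = unit_rows$unit_id[i], time = tt)
  }

  sess <- rgc_session(dplyr::bind_rows(spike_list), protocol,
                      genotype = genotype, zt = zt,
                      regime = protocol$regime, retina_id = retina_id)
  attr(sess, "truth") <- dplyr::select(unit_rows, "unit_id", "cell_class",
                                       "subtype")
  sess
}

#' Ground-truth class table of a simulated session
#' @param session A [simulate_session()] result.
#' @return Tibble `unit_id`, `cell_class`, `subtype`.
#' @export
session_truth <- function(session) {
  tr <- attr(session, "truth")
  if (is.null(tr)) stop("session carries no ground truth", call. = FALSE)
  tr
}

#' Default clock-gene expression parameters
#'
#' Cosine parameters emulating retinal clock-gene rhythms: Bmal1 and Dbp
#' peaking near ZT6, Per1 and Cry1 near ZT12; the knockout phase shift
#' (acrophase advance, h) defaults to -4 for all genes except Dbp, whose
#' oscillation is unchanged.
#'
#' @return Tibble `gene`, `baseline`, `amplitude`, `acrophase`, `sigma`,
#'   `cko_shift_h`.
#' @export
default_gene_params <- function() {
  tibble::tibble(
    gene = c("Bmal1", "Dbp", "Per1", "Cry1"),
    baseline = 1,
    amplitude = c(0.5, 0.8, 0.5, 0.4),
    acrophase = c(6, 6, 12, 12),
    sigma = 0.2 * c(0.5, 0.8, 0.5, 0.4),
    cko_shift_h = c(-4, 0, -4, -4)
  )
}

#' Simulate a clock-gene expression table
#'
#' Values are `baseline + amplitude * cos(2 pi (t - acrophase) / 24) +
#' N(0, sigma)` at ZT 0/6/12/18; the knockout acrophase is the control one
#' plus `cko_shift_h`.
#'
#' @param gene_params Tibble as [default_gene_params()].
#' @param n_per_zt Replicates (animals) per genotype per ZT.
#' @param seed Integer seed.
#' @param zts Sampling times (h).
#' @param output `"fold"` (column `value`) or `"ct"` (adds `ct_target`,
#'   `ct_housekeeping` columns encoding the same fold changes with a
#'   housekeeping Ct of 20 cycles).
#' @return Tibble `gene`, `genotype`, `zt`, `replicate`, `value` (and Ct
#'   columns when requested).
#' @export
simulate_expression <- function(gene_params = default_gene_params(),
                                n_per_zt = 6, seed = 1,
                                zts = c(0, 6, 12, 18),
                                output = c("fold", "ct")) {
  output <- match.arg(output)
  stopifnot(all(gene_params$sigma >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 1))
  grid <- tidyr::crossing(
    gene_params,
    genotype = c("Ctrl", "cKO"),
    zt = zts,
    replicate = seq_len(n_per_zt)
  )
  acro <- grid$acrophase + ifelse(grid$genotype == "cKO", grid$cko_shift_h, 0)
  mu <- grid$baseline + grid$amplitude * cos(2 * pi * (grid$zt - acro) / 24)
  grid$value <- mu + stats::rnorm(nrow(grid), 0, grid$sigma)
  out <- dplyr::select(grid, "gene", "genotype", "zt", "replicate", "value")
  if (output == "ct") {
    out$ct_housekeeping <- 20
    # fold = 2^-(dCt - ref); encode dCt = -log2(value) so ctrl ZT0 mean fold ~ baseline
    out$ct_target <- out$ct_housekeeping - log2(pmax(out$value, 1e-6))
  }
  out
}

#' Simulate a flash-ERG waveform with known wave amplitudes
#'
#' The waveform descends smoothly (raised cosine) from baseline to the
#' a-trough (depth `a_amp` at `a_latency`), rises smoothly by `b_amp` to the
#' b-peak at `b_latency`, then relaxes slowly toward baseline. Because the
#' trace does not return to baseline between the two waves, the extracted
#' amplitudes (baseline-to-trough and trough-to-peak) equal the parameters
#' exactly at zero noise for any combination of `a_amp` and `b_amp`.
#'
#' @param a_amp,b_amp Wave amplitudes (uV), >= 0.
#' @param a_latency,b_latency Trough and peak times (s), `a_latency <
#'   b_latency`; place them on the sampling grid for the exact round-trip
#'   property.
#' @param noise_sd Additive Gaussian noise SD (uV).
#' @param sampling_rate Hz.
#' @param pre_trial,duration Baseline window and post-flash span (s).
#' @param baseline Constant offset (uV).
#' @param tail_frac Fraction of the b-wave recovered toward baseline by the
#'   end of the trace (keeps the b-peak a strict maximum).
#' @param seed Integer seed (used only when `noise_sd > 0`).
#' @return An [erg_trace()].
#' @export
simulate_erg <- function(a_amp = 150, b_amp = 300,
                         a_latency = 0.020, b_latency = 0.100,
                         noise_sd = 0, sampling_rate = 2000,
                         pre_trial = 0.05, duration = 0.45,
                         baseline = 0, tail_frac = 0.3, seed = 1) {
  stopifnot(a_amp >= 0, b_amp >= 0, a_latency > 0, b_latency > a_latency)
  dt <- 1 / sampling_rate
  time <- seq(-pre_trial, duration, by = dt)
  ramp <- function(t, t0, t1) {
    # smooth 0 -> 1 over [t0, t1]
    z <- pmin(pmax((t - t0) / (t1 - t0), 0), 1)
    (1 - cos(pi * z)) / 2
  }
  v <- baseline - a_amp * ramp(time, 0, a_latency) +
    b_amp * ramp(time, a_latency, b_latency)
  tail <- time > b_latency
  v[tail] <- v[tail] - tail_frac * b_amp *
    (time[tail] - b_latency) / (duration - b_latency)
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(derive_seed(seed, 2))
    v <- v + stats::rnorm(length(v), 0, noise_sd)
  }
  erg_trace(time, v, condition = "photopic")
}

#' Default polarity-maintenance probabilities
#'
#' Probabilities that a unit keeps its mesopic label when re-recorded in the
#' photopic regime, per class and genotype; encodes the qualitative study
#' conditions (OFF maintenance reduced in the knockout, mainly by a raised
#' switch probability at ZT0).
#'
#' @return Tibble `class`, `genotype`, `zt`, `p_maintain`, `p_na`.
#' @export
default_maintenance_probs <- function() {
  base <- tidyr::crossing(
    class = c("ON", "ONOFF", "OFF"),
    genotype = c("Ctrl", "cKO"),
    zt = c(0, 6, 12, 18)
  )
  base$p_maintain <- dplyr::case_when(
    base$class == "ON" ~ 0.37,
    base$class == "ONOFF" ~ 0.55,
    base$class == "OFF" & base$genotype == "Ctrl" ~ 0.65,
    base$class == "OFF" & base$genotype == "cKO" & base$zt == 0 ~ 0.30,
    base$class == "OFF" & base$genotype == "cKO" & base$zt == 18 ~ 0.65,
    TRUE ~ 0.50
  )
  base$p_na <- 0.05
  base
}

#' Simulate matched-regime polarity label pairs
#'
#' Draws, for `n_per_cell` units in every (class, genotype, ZT) cell, a
#' mesopic label equal to the cell's class and a photopic label that is the
#' same with probability `p_maintain`, a different class otherwise, or `NA`
#' with probability `p_na` (template match failed in one regime).
#'
#' @param probs Tibble from [default_maintenance_probs()].
#' @param n_per_cell Units per (class, genotype, ZT) cell.
#' @param seed Integer seed.
#' @return Tibble `unit_id`, `genotype`, `zt`, `label_mesopic`,
#'   `label_photopic`, `category`, `class` (as from
#'   [match_units_across_regimes()]).
#' @export
simulate_polarity_pairs <- function(probs = default_maintenance_probs(),
                                    n_per_cell = 100, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, 3))
  classes <- c("ON", "ONOFF", "OFF")
  rows <- purrr::map_dfr(seq_len(nrow(probs)), function(i) {
    pr <- probs[i, ]
    u <- stats::runif(n_per_cell)
    photopic <- character(n_per_cell)
    na_cut <- pr$p_na
    keep_cut <- pr$p_na + (1 - pr$p_na) * pr$p_maintain
    others <- setdiff(classes, pr$class)
    photopic[u < na_cut] <- NA_character_
    photopic[u >= na_cut & u < keep_cut] <- pr$class
    n_sw <- sum(u >= keep_cut)
    photopic[u >= keep_cut] <- sample(others, n_sw, replace = TRUE)
    tibble::tibble(
      genotype = pr$genotype, zt = pr$zt,
      label_mesopic = pr$class, label_photopic = photopic
    )
  })
  rows$unit_id <- sprintf("pair_u%05d", seq_len(nrow(rows)))
  rows$category <- dplyr::case_when(
    is.na(rows$label_photopic) ~ "NA",
    rows$label_mesopic == rows$label_photopic ~ "maintained",
    TRUE ~ "switched"
  )
  rows$class <- rows$label_mesopic
  rows[, c("unit_id", "genotype", "zt", "label_mesopic", "label_photopic",
           "category", "class")]
}

#' Simulate a full study cohort
#'
#' One simulated session per (genotype, ZT, retina) cell under a shared
#' protocol, emulating the study grid at reduced unit counts.
#'
#' @param n_retinae_per_cell Retinae per (genotype, ZT).
#' @param counts Unit counts per class per retina.
#' @param protocol Shared stimulation protocol.
#' @param effects Gain effect table.
#' @param models Kinetic models.
#' @param seed Master seed; each session derives its own sub-seed.
#' @return List of [rgc_session()] objects.
#' @export
simulate_cohort <- function(n_retinae_per_cell = 3,
                            counts = c(ON = 50, OFF = 20, ONOFF = 40),
                            protocol = build_flash_protocol("mesopic"),
                            effects = default_effects(),
                            models = default_kinetic_models(),
                            seed = 1) {
  grid <- tidyr::crossing(genotype = c("Ctrl", "cKO"), zt = c(0, 6, 12, 18),
                          rep = seq_len(n_retinae_per_cell))
  purrr::pmap(grid, function(genotype, zt, rep) {
    id <- sprintf("%s_ZT%02d_r%d", genotype, zt, rep)
    simulate_session(
      counts = counts, protocol = protocol, genotype = genotype, zt = zt,
      models = models, effects = effects, retina_id = id,
      seed = derive_seed(seed, 17 * zt + 3 * rep + (genotype == "cKO") * 1000)
    )
  })
}
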