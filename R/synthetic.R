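# Synthetic-data generators: discontinuous LFP (1/f background + tapered
# oscillatory bursts + injectable cross-regional phase-amplitude coupling),
# paired spike trains with controlled dependence, behavior logs with
# controlled novelty preference, and whole cohorts with per-group effect
# multipliers. Every generator is a pure function of its spec and seed, and
# returns ground truth sufficient to score any downstream detector.

#' Pink (1/f) noise
#'
#' Gaussian noise spectrally shaped to `1/f^exponent` power, scaled to a
#' target standard deviation.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param exponent Spectral exponent (1 = pink, default).
#' @param sd Target SD of the output.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, fs, exponent = 1, sd = 1) {
  white <- rnorm(n)
  X <- fft(white)
  f <- seq(0, n - 1) / n * fs
  f <- pmin(f, fs - f)
  gain <- c(0, 1 / f[-1]^(exponent / 2))
  x <- Re(fft(X * gain, inverse = TRUE) / n)
  x / sqrt(mean((x - mean(x))^2)) * sd
}

tukey_window <- function(n, alpha = 0.25) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

#' Simulation spec for a discontinuous two-region LFP recording
#'
#' Defaults emulate a 30-minute neonatal PL/HP recording at the 100 Hz
#' analysis rate: pink background of 15 uV SD, and 10 Hz oscillatory bursts of
#' 200 uV amplitude occurring 1.5 times per minute with lognormal durations of
#' about one second, shared between the regions.
#'
#' @param duration_s Recording length (default 1800 s).
#' @param fs Sampling rate (default 100 Hz).
#' @param noise List: `exponent` (default 1), `sd_uV` (default 15).
#' @param bursts Data frame of burst families (`center_hz`, `amplitude_uV`,
#'   `meanlog`, `sdlog`, `rate_per_min`), or `NULL` for no bursts.
#' @param pac `NULL` (default) or a list `phase_hz`, `amp_hz`, `depth` in
#'   `[0, 1]`, `carrier_uV`, `phase_uV`: a continuous phase rhythm on HP whose
#'   phase modulates the envelope of a carrier on PL as
#'   `(1 + depth * cos(phase)) / 2`.
#' @param shared_bursts Probability that a burst appears in both regions
#'   (default 1; unshared bursts are assigned to one region at random).
#' @param seed Optional integer seed.
#' @return An `lfp_sim_spec` list.
#' @export
lfp_sim_spec <- function(duration_s = 1800, fs = 100,
                         noise = list(exponent = 1, sd_uV = 15),
                         bursts = tibble::tibble(center_hz = 10,
                                                 amplitude_uV = 200,
                                                 meanlog = log(1),
                                                 sdlog = 0.3,
                                                 rate_per_min = 1.5),
                         pac = NULL, shared_bursts = 1, seed = NULL) {
  if (!is.null(pac)) {
    if (pac$depth < 0 || pac$depth > 1) {
      abort("pac depth must lie in [0, 1]", class = "neodev_param_error")
    }
    pac$carrier_uV <- pac$carrier_uV %||% 30
    pac$phase_uV <- pac$phase_uV %||% 30
  }
  if (!is.null(bursts) && any(bursts$amplitude_uV <= 0 | bursts$rate_per_min <= 0)) {
    abort("burst amplitudes and rates must be positive",
          class = "neodev_param_error")
  }
  structure(list(duration_s = duration_s, fs = fs, noise = noise,
                 bursts = bursts, pac = pac, shared_bursts = shared_bursts,
                 seed = seed),
            class = "lfp_sim_spec")
}

# Place `count` bursts in equal slots with jitter, guaranteeing >= 1.5 s
# separation so ground-truth intervals never interact with the 1 s merge rule.
place_bursts <- function(count, duration_s, meanlog, sdlog) {
  slot <- duration_s / count
  starts <- durs <- numeric(count)
  for (i in seq_len(count)) {
    d <- min(max(rlnorm(1, meanlog, sdlog), 0.4), slot - 2)
    s0 <- (i - 1) * slot
    starts[i] <- s0 + 0.5 + runif(1) * max(slot - d - 2, 0)
    durs[i] <- d
  }
  list(start = starts, dur = durs)
}

#' Generate a discontinuous two-region LFP recording with ground truth
#'
#' Bursts are Tukey-tapered (alpha = 0.25) sinusoids added to pink noise at
#' annotated intervals; the annotation count equals the realized burst count.
#' When `spec$pac` is set, a continuous `phase_hz` rhythm is added to the HP
#' channel and a `amp_hz` carrier whose envelope follows
#' `(1 + depth * cos(phase)) / 2` of that rhythm is added to the PL channel.
#' Fully reproducible from `spec$seed`.
#'
#' @param spec An [lfp_sim_spec()].
#' @return List: `recording` (channels `pl1`, `hp1`) and `truth`, an interval
#'   tibble with one row per injected burst per channel (overlapping injected
#'   bursts are merged, consistent with detector semantics).
#' @export
gen_lfp <- function(spec) {
  stopifnot(inherits(spec, "lfp_sim_spec"))
  with_seed(spec$seed, {
    n <- as.integer(round(spec$duration_s * spec$fs))
    t <- (seq_len(n) - 1) / spec$fs
    pl <- pink_noise(n, spec$fs, spec$noise$exponent, spec$noise$sd_uV)
    hp <- pink_noise(n, spec$fs, spec$noise$exponent, spec$noise$sd_uV)
    truth <- tibble::tibble(start_s = numeric(), end_s = numeric(),
                            label = character(), channel_id = character(),
                            value = numeric())
    if (!is.null(spec$bursts)) {
      for (b in seq_len(nrow(spec$bursts))) {
        bb <- spec$bursts[b, ]
        count <- max(1L, as.integer(round(bb$rate_per_min *
                                            spec$duration_s / 60)))
        pos <- place_bursts(count, spec$duration_s, bb$meanlog, bb$sdlog)
        for (i in seq_len(count)) {
          i0 <- as.integer(floor(pos$start[i] * spec$fs)) + 1L
          len <- as.integer(round(pos$dur[i] * spec$fs))
          idx <- i0:min(i0 + len - 1L, n)
          phase0 <- runif(1, 0, 2 * pi)
          wave <- bb$amplitude_uV *
            sin(2 * pi * bb$center_hz * t[idx] + phase0) *
            tukey_window(length(idx), 0.25)
          shared <- runif(1) < spec$shared_bursts
          chans <- if (shared) c("pl1", "hp1") else
            sample(c("pl1", "hp1"), 1)
          if ("pl1" %in% chans) pl[idx] <- pl[idx] + wave
          if ("hp1" %in% chans) hp[idx] <- hp[idx] + wave
          truth <- dplyr::bind_rows(truth, tibble::tibble(
            start_s = pos$start[i], end_s = pos$start[i] + pos$dur[i],
            label = "burst", channel_id = chans,
            value = bb$amplitude_uV))
        }
      }
      # merge overlapping injected bursts per channel
      truth <- truth |>
        dplyr::group_by(.data$channel_id) |>
        dplyr::group_modify(function(d, key) {
          m <- merge_gaps(d$start_s, d$end_s, gap_s = 0)
          tibble::tibble(start_s = m$starts, end_s = m$ends,
                         label = "burst",
                         value = max(d$value))
        }) |>
        dplyr::ungroup() |>
        dplyr::arrange(.data$channel_id, .data$start_s)
    }
    if (!is.null(spec$pac)) {
      pc <- spec$pac
      phase <- 2 * pi * pc$phase_hz * t
      hp <- hp + pc$phase_uV * sin(phase)
      env <- (1 + pc$depth * cos(phase)) / 2
      pl <- pl + pc$carrier_uV * env * sin(2 * pi * pc$amp_hz * t)
    }
    rec <- recording(rbind(pl, hp), fs = spec$fs,
                     channels = tibble::tibble(
                       channel_id = c("pl1", "hp1"),
                       region = c("PL", "HP")),
                     units = "uV")
    list(recording = rec, truth = truth)
  })
}

#' Generate a pair of spike trains with controlled dependence
#'
#' Region A counts are Poisson per bin; region B counts are the sum of an
#' independent Poisson component with rate `(1 - coupling) * rate` and a
#' binomial thinning of A's realized counts with probability `coupling`, so
#' both marginal rates equal `rate_hz` and the binned mutual information is
#' monotone in `coupling`. At `coupling = 1`, B's counts equal A's exactly.
#'
#' @param rate_hz Marginal firing rate per region (Hz).
#' @param coupling Dependence strength in `[0, 1]`.
#' @param duration_s Recording duration (s).
#' @param bin_s Bin width (default 0.05 s).
#' @param seed Optional integer seed.
#' @return List: `spikes` (tibble `time_s`, `channel_id` in `pl_mua`,
#'   `hp_mua`, with `duration_s` attribute), `channels` (channel/region map),
#'   and the realized per-bin counts `counts_pl`, `counts_hp`.
#' @export
gen_coupled_spike_trains <- function(rate_hz, coupling, duration_s,
                                     bin_s = 0.05, seed = NULL) {
  if (coupling < 0 || coupling > 1) {
    abort("coupling must lie in [0, 1]", class = "neodev_param_error")
  }
  lambda <- rate_hz * bin_s
  if (lambda > 20) warn("more than 20 expected counts per bin")
  with_seed(seed, {
    n_bins <- floor(duration_s / bin_s)
    a <- rpois(n_bins, lambda)
    b <- rpois(n_bins, (1 - coupling) * lambda) + rbinom(n_bins, a, coupling)
    times <- function(counts, id) {
      idx <- rep(seq_len(n_bins) - 1, counts)
      tibble::tibble(time_s = sort((idx + runif(length(idx))) * bin_s),
                     channel_id = id)
    }
    spikes <- dplyr::bind_rows(times(a, "pl_mua"), times(b, "hp_mua"))
    attr(spikes, "duration_s") <- duration_s
    list(spikes = spikes,
         channels = tibble::tibble(channel_id = c("pl_mua", "hp_mua"),
                                   region = c("PL", "HP")),
         counts_pl = a, counts_hp = b)
  })
}

#' Generate an object-interaction log with controlled novelty preference
#'
#' Each bout is assigned to the novel object with probability
#' `(1 + preference) / 2` and given an exponential duration, so the expected
#' discrimination ratio of the log equals `preference` up to sampling error.
#'
#' @param preference Target discrimination ratio in `[-1, 1]`.
#' @param n_bouts Number of interaction bouts.
#' @param mean_bout_s Mean bout duration (s).
#' @param seed Optional integer seed.
#' @return Tibble `bout`, `object` (`"novel"`/`"familiar"`), `duration_s`.
#' @export
gen_behavior <- function(preference, n_bouts, mean_bout_s = 2, seed = NULL) {
  if (preference < -1 || preference > 1) {
    abort("preference must lie in [-1, 1]", class = "neodev_param_error")
  }
  if (n_bouts == 0) {
    warn("n_bouts = 0: empty interaction log")
    return(tibble::tibble(bout = integer(), object = character(),
                          duration_s = numeric()))
  }
  with_seed(seed, {
    obj <- ifelse(runif(n_bouts) < (1 + preference) / 2, "novel", "familiar")
    tibble::tibble(bout = seq_len(n_bouts), object = obj,
                   duration_s = rexp(n_bouts, 1 / mean_bout_s))
  })
}

#' Cohort simulation spec
#'
#' Describes a multi-group study design: per-group sample sizes and effect
#' multipliers on burst amplitude, burst rate, phase-amplitude coupling depth,
#' and spike coupling, plus per-group behavioral preference. The defaults
#' encode a two-group design with no effect (all multipliers 1).
#'
#' @param groups Tibble with columns `group`, `n`, and optionally `amp_mult`,
#'   `rate_mult`, `pac_mult`, `coupling_mult`, `preference` (defaults 1, 1, 1,
#'   1, 0.3).
#' @param lfp Base [lfp_sim_spec()] shared by all animals (seed ignored).
#' @param spike_rate_hz Base marginal MUA rate (default 4 Hz).
#' @param spike_coupling Base spike coupling (default 0.3).
#' @param n_bouts,mean_bout_s Behavior log parameters.
#' @param master_seed Master seed; per-animal seeds derive deterministically
#'   from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(groups = tibble::tibble(group = c("MMcpos", "MMclow"),
                                                n = c(12, 12)),
                        lfp = lfp_sim_spec(), spike_rate_hz = 4,
                        spike_coupling = 0.3, n_bouts = 40, mean_bout_s = 2,
                        master_seed = 1) {
  groups <- tibble::as_tibble(groups)
  defaults <- list(amp_mult = 1, rate_mult = 1, pac_mult = 1,
                   coupling_mult = 1, preference = 0.3)
  for (nm in names(defaults)) {
    if (!nm %in% names(groups)) groups[[nm]] <- defaults[[nm]]
  }
  if (any(groups$n < 1)) abort("group n must be >= 1",
                               class = "neodev_param_error")
  if (any(groups$amp_mult <= 0 | groups$rate_mult <= 0 |
            groups$coupling_mult <= 0)) {
    abort("multipliers must be positive", class = "neodev_param_error")
  }
  structure(list(groups = groups, lfp = lfp, spike_rate_hz = spike_rate_hz,
                 spike_coupling = spike_coupling, n_bouts = n_bouts,
                 mean_bout_s = mean_bout_s, master_seed = master_seed),
            class = "cohort_spec")
}

#' Generate a full synthetic cohort
#'
#' Applies each group's multipliers to the base simulation parameters and
#' generates per animal: a two-region LFP recording with burst ground truth,
#' paired spike trains, and a behavior log. Per-animal seeds derive
#' deterministically from the master seed, so a fixed spec reproduces the
#' cohort exactly.
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with one row per animal: `animal_id`, `group`, `seed`, and
#'   list-columns `recording`, `truth`, `spikes`, `channels`, `behavior`.
#' @export
gen_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  rows <- list()
  idx <- 0L
  for (g in seq_len(nrow(spec$groups))) {
    grp <- spec$groups[g, ]
    for (i in seq_len(grp$n)) {
      idx <- idx + 1L
      seed <- derive_seed(spec$master_seed, idx)
      lfp <- spec$lfp
      if (!is.null(lfp$bursts)) {
        lfp$bursts$amplitude_uV <- lfp$bursts$amplitude_uV * grp$amp_mult *
          with_seed(seed, rlnorm(nrow(lfp$bursts), 0, 0.15))
        lfp$bursts$rate_per_min <- lfp$bursts$rate_per_min * grp$rate_mult
      }
      if (!is.null(lfp$pac)) {
        lfp$pac$depth <- min(1, lfp$pac$depth * grp$pac_mult)
      }
      lfp$seed <- derive_seed(seed, 1L)
      sim <- gen_lfp(lfp)
      spk <- gen_coupled_spike_trains(
        spec$spike_rate_hz, min(1, spec$spike_coupling * grp$coupling_mult),
        duration_s = lfp$duration_s, seed = derive_seed(seed, 2L))
      beh <- gen_behavior(grp$preference, spec$n_bouts, spec$mean_bout_s,
                          seed = derive_seed(seed, 3L))
      rows[[idx]] <- tibble::tibble(
        animal_id = sprintf("%s_%02d", grp$group, i), group = grp$group,
        seed = seed, recording = list(sim$recording), truth = list(sim$truth),
        spikes = list(spk$spikes), channels = list(spk$channels),
        behavior = list(beh))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$animal_id)) {
    abort("duplicate animal ids", class = "neodev_validation_error")
  }
  out
}
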