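# Per-animal feature extraction and cohort-level comparison: compose the
# detection, spectral, coupling, spiking, and behavior modules into a feature
# table, then run the nonparametric battery per feature.

#' Pipeline configuration
#'
#' Bundles all module configurations plus the feature manifest naming which
#' features [run_animal()] computes.
#'
#' @param detection A [detection_config()].
#' @param bands A [band_scheme()].
#' @param window_s Welch window length (s) for PSD and coherence.
#' @param pac List: `amp_range`, `phase_range` (Hz) for the coupling summary,
#'   `phase_freqs`/`amp_freqs` grids (`NULL` = defaults), `n_bins`.
#' @param mua A [mua_config()] (used when raw MUA-band recordings are given).
#' @param bin_s Spike-count bin width (default 0.05 s).
#' @param features Character manifest; any subset of the default set.
#' @param exclude_outliers Apply the 10th/90th percentile rule per group per
#'   feature before testing (default `TRUE`).
#' @param adjust Post-hoc adjustment for multi-group designs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(detection = detection_config(),
                            bands = band_scheme(), window_s = 1,
                            pac = list(amp_range = c(20, 30),
                                       phase_range = c(4, 12),
                                       phase_freqs = NULL, amp_freqs = NULL,
                                       n_bins = 18),
                            mua = mua_config(), bin_s = 0.05,
                            features = default_features(),
                            exclude_outliers = TRUE, adjust = "bonferroni") {
  unknown <- setdiff(features, default_features())
  if (length(unknown) > 0) {
    abort(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
          class = "neodev_param_error")
  }
  structure(list(detection = detection, bands = bands, window_s = window_s,
                 pac = pac, mua = mua, bin_s = bin_s, features = features,
                 exclude_outliers = exclude_outliers, adjust = adjust),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
default_features <- function() {
  c(paste0(rep(c("pl", "hp"), each = 4), "_",
           rep(c("amplitude_uV", "mean_duration_s", "periods_per_min",
                 "fraction_active"), 2)),
    paste0(rep(c("pl", "hp"), each = 3), "_",
           rep(c("theta_power", "beta_power", "gamma_power"), 2)),
    paste0("icoh_", c("theta", "beta", "gamma")),
    "pac_20_30",
    "pl_firing_rate_hz", "hp_firing_rate_hz",
    "pl_entropy_bits", "hp_entropy_bits", "mi_bits",
    "discrimination_time", "discrimination_count")
}

#' Build a pipeline configuration from a YAML file
#'
#' Recognized keys mirror the module parameters, e.g. `detection.mode`,
#' `detection.upper_threshold`, `preprocess.lfp_band`, `spectral.window_s`,
#' `features`.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  det_args <- y$detection %||% list()
  if (!is.null(y$preprocess$lfp_band)) {
    det_args$detect_band <- as.numeric(y$preprocess$lfp_band)
  }
  if (!is.null(y$preprocess$detect_fs)) {
    det_args$detect_fs <- y$preprocess$detect_fs
  }
  pipeline_config(
    detection = do.call(detection_config, det_args),
    window_s = y$spectral$window_s %||% 1,
    bin_s = y$spiking$bin_s %||% 0.05,
    features = y$features %||% default_features()
  )
}

#' Extract all manifest features for one animal
#'
#' Runs detection, spectral, coupling, spiking, and behavior measures on one
#' animal's data and returns a single feature row. Each feature group is
#' fail-soft: an error in one measure records the reason (in the
#' `feature_errors` attribute) and leaves its features missing rather than
#' aborting the animal. Missing inputs (e.g. no behavior log) simply leave the
#' corresponding features `NA`.
#'
#' @param recording A [recording()] or path readable by [read_recording()].
#' @param spikes Spike tibble (with `duration_s` attribute) or path.
#' @param channels Channel/region map for the spike electrodes (defaults to
#'   the recording's channel table).
#' @param behavior Interaction-bout tibble (`object`, `duration_s`) or path.
#' @param cfg A [pipeline_config()].
#' @param animal_id,group Identifier columns copied into the row.
#' @return One-row feature tibble; attribute `feature_errors` lists per-feature
#'   failures.
#' @export
run_animal <- function(recording = NULL, spikes = NULL, channels = NULL,
                       behavior = NULL, cfg = pipeline_config(),
                       animal_id = "animal", group = NA_character_) {
  if (is.character(recording)) recording <- read_recording(recording)
  if (is.character(spikes)) spikes <- read_spikes(spikes)
  if (is.character(behavior)) {
    behavior <- tibble::as_tibble(utils::read.csv(behavior,
                                                  check.names = FALSE))
  }
  feats <- list(animal_id = animal_id, group = group)
  errors <- list()
  want <- function(x) any(x %in% cfg$features)
  periods <- list(pl = NULL, hp = NULL)

  if (!is.null(recording)) {
    dur <- duration(recording)
    for (rg in c("pl", "hp")) {
      region <- toupper(rg)
      pf_names <- paste0(rg, "_", c("amplitude_uV", "mean_duration_s",
                                    "periods_per_min", "fraction_active"))
      bp_names <- paste0(rg, "_", c("theta_power", "beta_power",
                                    "gamma_power"))
      if (!region %in% recording$channels$region) next
      ch <- region_channel(recording, region)
      if (want(c(pf_names, bp_names, "icoh_theta", "pac_20_30"))) {
        res <- tryCatch({
          p <- detect_active_periods(recording, cfg$detection,
                                     channel_id = ch)
          periods[[rg]] <- p
          pf <- period_features(p, dur)
          stats::setNames(unlist(pf[1, ]), pf_names)
        }, error = function(e) {
          errors[[length(errors) + 1L]] <<-
            paste(rg, "periods:", conditionMessage(e))
          stats::setNames(rep(NA_real_, 4), pf_names)
        })
        for (nm in pf_names) feats[[nm]] <- unname(res[[nm]])
      }
      if (want(bp_names)) {
        res <- tryCatch({
          psd <- psd_over_periods(recording, periods[[rg]], cfg$window_s,
                                  channel_id = ch)
          vapply(cfg$bands, function(b) {
            band_power(psd, c(b[1], min(b[2], max(psd$freq_hz))))
          }, numeric(1))
        }, error = function(e) {
          errors[[length(errors) + 1L]] <<-
            paste(rg, "band power:", conditionMessage(e))
          stats::setNames(rep(NA_real_, 3), names(cfg$bands))
        })
        for (i in seq_along(cfg$bands)) {
          feats[[paste0(rg, "_", names(cfg$bands)[i], "_power")]] <-
            unname(res[[i]])
        }
      }
    }
    icoh_names <- paste0("icoh_", names(cfg$bands))
    if (want(icoh_names) &&
        all(c("PL", "HP") %in% recording$channels$region)) {
      res <- tryCatch({
        joint <- dplyr::bind_rows(periods$pl, periods$hp)
        ic <- icoh_over_periods(recording, joint, cfg$window_s)
        vapply(cfg$bands, function(b) {
          sel <- ic$freq_hz >= b[1] & ic$freq_hz < min(b[2], recording$fs / 2)
          mean(ic$icoh[sel])
        }, numeric(1))
      }, error = function(e) {
        errors[[length(errors) + 1L]] <<-
          paste("icoh:", conditionMessage(e))
        stats::setNames(rep(NA_real_, length(cfg$bands)), names(cfg$bands))
      })
      for (i in seq_along(cfg$bands)) {
        feats[[icoh_names[i]]] <- unname(res[[i]])
      }
    }
    if (want("pac_20_30") &&
        all(c("PL", "HP") %in% recording$channels$region)) {
      feats$pac_20_30 <- tryCatch({
        com <- pac_comodulogram(
          channel_trace(recording, region_channel(recording, "HP")),
          channel_trace(recording, region_channel(recording, "PL")),
          recording$fs, phase_freqs = cfg$pac$phase_freqs,
          amp_freqs = cfg$pac$amp_freqs, n_bins = cfg$pac$n_bins %||% 18,
          periods = dplyr::bind_rows(periods$pl, periods$hp))
        pac_band_average(com, cfg$pac$amp_range, cfg$pac$phase_range)
      }, error = function(e) {
        errors[[length(errors) + 1L]] <<- paste("pac:", conditionMessage(e))
        NA_real_
      })
    }
  }

  if (!is.null(spikes)) {
    chtab <- channels %||% recording$channels
    dur_s <- attr(spikes, "duration_s") %||%
      (if (!is.null(recording)) duration(recording) else NULL)
    res <- tryCatch({
      binned <- lapply(c(PL = "PL", HP = "HP"), function(rgn) {
        bin_spikes(spikes, chtab, rgn, cfg$bin_s, duration_s = dur_s)
      })
      c(pl_firing_rate_hz = firing_rate(
          spikes[spikes$channel_id %in%
                   chtab$channel_id[chtab$region == "PL"], ], 0, dur_s),
        hp_firing_rate_hz = firing_rate(
          spikes[spikes$channel_id %in%
                   chtab$channel_id[chtab$region == "HP"], ], 0, dur_s),
        pl_entropy_bits = entropy(binned$PL),
        hp_entropy_bits = entropy(binned$HP),
        mi_bits = mutual_information(binned$PL, binned$HP))
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- paste("spiking:", conditionMessage(e))
      stats::setNames(rep(NA_real_, 5),
                      c("pl_firing_rate_hz", "hp_firing_rate_hz",
                        "pl_entropy_bits", "hp_entropy_bits", "mi_bits"))
    })
    for (nm in names(res)) {
      if (nm %in% cfg$features) feats[[nm]] <- unname(res[[nm]])
    }
  }

  if (!is.null(behavior) && nrow(behavior) > 0 &&
      want(c("discrimination_time", "discrimination_count"))) {
    res <- tryCatch({
      tn <- sum(behavior$duration_s[behavior$object == "novel"])
      tf <- sum(behavior$duration_s[behavior$object == "familiar"])
      cn <- sum(behavior$object == "novel")
      cf <- sum(behavior$object == "familiar")
      c(discrimination_time = discrimination_ratio(tn, tf),
        discrimination_count = discrimination_ratio(cn, cf))
    }, error = function(e) {
      errors[[length(errors) + 1L]] <<- paste("behavior:", conditionMessage(e))
      c(discrimination_time = NA_real_, discrimination_count = NA_real_)
    })
    for (nm in names(res)) {
      if (nm %in% cfg$features) feats[[nm]] <- unname(res[[nm]])
    }
  }

  out <- tibble::as_tibble(feats)
  attr(out, "feature_errors") <- unlist(errors)
  out
}

#' Run the full cohort analysis
#'
#' Extracts the manifest features for every animal and compares groups per
#' feature: per-group percentile outlier exclusion (optional), then the test
#' chosen by the auto rule - two groups: Mann-Whitney U; three or more:
#' Kruskal-Wallis with Dunn's post hoc. Features with fewer than two
#' non-missing values in any group are skipped with a reason.
#'
#' @param cohort Tibble as from [gen_cohort()] (columns `animal_id`, `group`,
#'   and list-columns `recording`, `spikes`, `channels`, `behavior`; missing
#'   list-columns are tolerated).
#' @param cfg A [pipeline_config()].
#' @return A `neodev_cohort_result`: list with `features` (one row per animal)
#'   and `stats` (one row per tested feature: `feature`, `method`,
#'   `statistic`, `p_value`, `n_used`, `n_excluded`, `pairwise` list-column,
#'   `skipped_reason`).
#' @export
run_cohort <- function(cohort, cfg = pipeline_config()) {
  if (length(unique(cohort$group)) < 2) {
    abort("need at least two groups", class = "neodev_param_error")
  }
  get_col <- function(row, nm) {
    if (nm %in% names(cohort)) cohort[[nm]][[row]] else NULL
  }
  features <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    run_animal(recording = get_col(i, "recording"),
               spikes = get_col(i, "spikes"),
               channels = get_col(i, "channels"),
               behavior = get_col(i, "behavior"),
               cfg = cfg, animal_id = cohort$animal_id[[i]],
               group = cohort$group[[i]])
  })
  stats_tbl <- purrr::map_dfr(cfg$features, function(fc) {
    vals <- if (fc %in% names(features)) features[[fc]] else
      rep(NA_real_, nrow(features))
    by_group <- split(vals,
                      factor(features$group, levels = unique(features$group)))
    by_group <- lapply(by_group, function(v) v[!is.na(v)])
    if (any(lengths(by_group) < 2)) {
      return(tibble::tibble(feature = fc, method = NA_character_,
                            statistic = NA_real_, p_value = NA_real_,
                            n_used = list(lengths(by_group)),
                            n_excluded = NA_integer_, pairwise = list(NULL),
                            skipped_reason = "fewer than 2 values in a group"))
    }
    n_before <- sum(lengths(by_group))
    if (cfg$exclude_outliers) {
      # percentile rule applied to the pooled feature values (group-blind):
      # trimming within groups would amplify chance group separation and
      # inflate the false-positive rate of the rank tests
      pooled <- unlist(by_group, use.names = FALSE)
      if (length(pooled) > 2) {
        q <- quantile(pooled, c(0.1, 0.9), type = 7, names = FALSE)
        by_group <- lapply(by_group, function(v) v[v >= q[1] & v <= q[2]])
      }
      if (any(lengths(by_group) < 2)) {
        return(tibble::tibble(feature = fc, method = NA_character_,
                              statistic = NA_real_, p_value = NA_real_,
                              n_used = list(lengths(by_group)),
                              n_excluded = n_before - sum(lengths(by_group)),
                              pairwise = list(NULL),
                              skipped_reason = "fewer than 2 values in a group after exclusion"))
      }
    }
    res <- if (length(by_group) == 2) {
      mann_whitney_u(by_group[[1]], by_group[[2]])
    } else {
      kruskal_dunn(by_group, adjust = cfg$adjust)
    }
    tibble::tibble(feature = fc, method = res$method,
                   statistic = res$statistic, p_value = res$p_value,
                   n_used = list(lengths(by_group)),
                   n_excluded = n_before - sum(lengths(by_group)),
                   pairwise = list(res$pairwise),
                   skipped_reason = NA_character_)
  })
  structure(list(features = features, stats = stats_tbl, config = cfg),
            class = "neodev_cohort_result")
}

#' @export
print.neodev_cohort_result <- function(x, ...) {
  cat(sprintf("<neodev_cohort_result> %d animals, %d features tested\n",
              nrow(x$features), sum(!is.na(x$stats$p_value))))
  print(dplyr::select(x$stats, "feature", "method", "statistic", "p_value"))
  invisible(x)
}
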