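# Behavioral scores from event logs and tracking tables: object interaction
# with a climbing exclusion, novelty discrimination ratios, Y-maze alternation
# metrics, marble burying index, open-field occupancy/locomotion, and
# scan-sampling nest occupancy.

#' Extract object-interaction bouts from a tracking table
#'
#' A frame counts as interacting when the head point is in the object zone but
#' head and center-of-gravity are not both in it (climbing/sitting exclusion).
#' Bouts are maximal runs of interacting frames; each non-interacting to
#' interacting transition counts as an entry.
#'
#' @param track Tibble with `t_s` (strictly increasing, fixed frame rate),
#'   `head_zone`, `cog_zone` (zone ids or `NA`).
#' @param object_zone Zone id of the object.
#' @param zones Known zone ids; unknown zones in the data are an error.
#' @param climbing_exclusion Apply the both-points rule (default `TRUE`).
#' @return One-row tibble: `object_zone`, `total_time_s`, `n_bouts`,
#'   `mean_bout_s`.
#' @export
extract_interactions <- function(track, object_zone, zones = NULL,
                                 climbing_exclusion = TRUE) {
  seen <- unique(c(track$head_zone, track$cog_zone))
  seen <- seen[!is.na(seen)]
  if (!is.null(zones) && length(setdiff(seen, zones)) > 0) {
    abort(sprintf("unknown zone(s): %s",
                  paste(setdiff(seen, zones), collapse = ", ")),
          class = "neodev_param_error")
  }
  dt <- diff(track$t_s)
  if (any(dt <= 0)) abort("t_s must be strictly increasing",
                          class = "neodev_validation_error")
  frame_s <- stats::median(dt)
  head_in <- !is.na(track$head_zone) & track$head_zone == object_zone
  both_in <- head_in & !is.na(track$cog_zone) & track$cog_zone == object_zone
  interacting <- if (climbing_exclusion) head_in & !both_in else head_in
  r <- rle(interacting)
  n_bouts <- sum(r$values)
  total <- sum(interacting) * frame_s
  tibble::tibble(object_zone = object_zone, total_time_s = total,
                 n_bouts = n_bouts,
                 mean_bout_s = if (n_bouts > 0) total / n_bouts else NA_real_)
}

#' Novelty discrimination ratio
#'
#' `(novel - familiar) / (novel + familiar)`, in `[-1, 1]`. Used identically
#' for interaction times, interaction counts, and single-interaction-time
#' summaries. Both inputs zero yields `NA` (undefined), never 0.
#'
#' @param time_novel_s,time_familiar_s Non-negative interaction measures for
#'   the novel (or less recent) and familiar object.
#' @return Dimensionless ratio in `[-1, 1]`, or `NA` if both are zero.
#' @export
discrimination_ratio <- function(time_novel_s, time_familiar_s) {
  if (any(time_novel_s < 0) || any(time_familiar_s < 0)) {
    abort("interaction measures must be non-negative",
          class = "neodev_param_error")
  }
  total <- time_novel_s + time_familiar_s
  out <- (time_novel_s - time_familiar_s) / total
  out[total == 0] <- NA_real_
  out
}

#' Y-maze alternation metrics
#'
#' Over all `n - 2` consecutive arm-entry triplets: spontaneous alternation
#' (all three arms distinct), alternate arm return (first equals third, second
#' different), and same arm return (third equals second). Each percentage is
#' the triplet count divided by `n - 2`, times 100.
#'
#' @param arm_sequence Character vector over the arms (default `A`, `B`, `C`),
#'   length >= 3.
#' @param arms Allowed arm labels.
#' @return One-row tibble: `spontaneous_pct`, `alternate_arm_return_pct`,
#'   `same_arm_return_pct`, `n_entries`.
#' @export
alternation_metrics <- function(arm_sequence, arms = c("A", "B", "C")) {
  n <- length(arm_sequence)
  if (n < 3) abort("need at least 3 arm entries", class = "neodev_param_error")
  if (!all(arm_sequence %in% arms)) {
    abort(sprintf("entries outside {%s}", paste(arms, collapse = ",")),
          class = "neodev_param_error")
  }
  a <- arm_sequence[1:(n - 2)]
  b <- arm_sequence[2:(n - 1)]
  c_ <- arm_sequence[3:n]
  spont <- a != b & b != c_ & a != c_
  aar <- a == c_ & a != b
  sar <- c_ == b
  tibble::tibble(
    spontaneous_pct = 100 * sum(spont) / (n - 2),
    alternate_arm_return_pct = 100 * sum(aar) / (n - 2),
    same_arm_return_pct = 100 * sum(sar) / (n - 2),
    n_entries = n
  )
}

#' Marble burying index
#'
#' Mean buried-marble count across observers at each timepoint. A marble
#' counts as buried when more than 75% of its volume is covered (an
#' observer-level scoring rule; this function averages the resulting counts).
#'
#' @param counts Tibble with `timepoint_min`, `observer`, `n_buried`
#'   (0 to `n_marbles`).
#' @param n_marbles Total marbles in the arena (default 20).
#' @return Tibble `timepoint_min`, `marble_index` (mean across observers).
#' @export
marble_index <- function(counts, n_marbles = 20) {
  if (any(counts$n_buried > n_marbles | counts$n_buried < 0)) {
    abort(sprintf("buried counts must lie in [0, %d]", n_marbles),
          class = "neodev_param_error")
  }
  counts |>
    dplyr::group_by(.data$timepoint_min) |>
    dplyr::summarise(marble_index = mean(.data$n_buried), .groups = "drop")
}

#' Open-field occupancy and locomotion metrics
#'
#' Zone occupancy from the center-of-gravity position by zone role (the arena
#' is divided into 4 center and 4 border zones), total path length as the sum
#' of Euclidean steps, and mean velocity.
#'
#' @param track Tibble with `t_s`, `x_cm`, `y_cm`, `cog_zone`.
#' @param zone_registry Tibble with `zone`, `role` (`"center"` or `"border"`).
#' @param arena_radius_cm Optional arena radius; positions outside produce a
#'   warning and are clamped for the distance computation.
#' @return One-row tibble: `time_center_s`, `time_border_s`, `distance_cm`,
#'   `velocity_cm_s`.
#' @export
openfield_metrics <- function(track, zone_registry, arena_radius_cm = NULL) {
  frame_s <- stats::median(diff(track$t_s))
  x <- track$x_cm; y <- track$y_cm
  if (!is.null(arena_radius_cm)) {
    r <- sqrt(x^2 + y^2)
    n_out <- sum(r > arena_radius_cm)
    if (n_out > 0) {
      warn(sprintf("%d position(s) outside arena bounds; clamped", n_out))
      f <- pmin(1, arena_radius_cm / pmax(r, 1e-12))
      x <- x * f; y <- y * f
    }
  }
  role <- zone_registry$role[match(track$cog_zone, zone_registry$zone)]
  dist <- sum(sqrt(diff(x)^2 + diff(y)^2))
  dur <- track$t_s[length(track$t_s)] - track$t_s[1] + frame_s
  tibble::tibble(
    time_center_s = sum(role == "center", na.rm = TRUE) * frame_s,
    time_border_s = sum(role == "border", na.rm = TRUE) * frame_s,
    distance_cm = dist,
    velocity_cm_s = dist / dur
  )
}

#' Scan-sampling nest occupancy
#'
#' Percentage of snapshots in which the dam was on the nest.
#'
#' @param snapshots Logical vector (on nest / off nest).
#' @return Percentage in `[0, 100]`.
#' @export
scan_sampling_proportion <- function(snapshots) {
  if (length(snapshots) == 0) abort("no snapshots",
                                    class = "neodev_param_error")
  100 * sum(snapshots) / length(snapshots)
}
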