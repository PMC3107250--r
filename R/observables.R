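# Per-run and batch observables. All are pure functions of the recorded
# trajectory/contact data, so they can be recomputed offline from saved
# tracks and give bit-identical results.

#' Radial probability distribution of the cargo in the channel
#'
#' Histograms the radial coordinate (distance from the pore axis in the
#' cross-sectional plane) over the samples with the cargo inside the central
#' channel, in 1 nm bins, and fits a Gaussian to report peak +- SD.
#'
#' @param track a cargo track tibble with columns `y` and `r` (or `x`), or
#'   a `transport_record`.
#' @param planes channel planes: list with `channel_top` and
#'   `channel_bottom` (taken from the record when one is given).
#' @param bin bin width in nm (default 1).
#' @return a `radial_histogram`: tibble of `r_lo`, `r_hi`, `r_mid`,
#'   `count`, `probability`, with attributes `peak` and `sd` from the
#'   Gaussian fit and `n` samples.
#' @export
radial_probability <- function(track, planes = NULL, bin = 1) {
  if (inherits(track, "transport_record")) {
    planes <- track$planes
    track <- track$track
  }
  stopifnot(!is.null(planes), bin > 0)
  r <- if ("r" %in% names(track)) track$r else abs(track$x)
  inside <- track$y < planes$channel_top & track$y > planes$channel_bottom
  r <- r[inside]
  if (length(r) == 0) {
    abort("no track samples inside the channel",
          class = "npcbd_empty_histogram")
  }
  edges <- seq(0, ceiling(max(r) / bin) * bin + bin, by = bin)
  cnt <- table(cut(r, edges, right = FALSE))
  out <- tibble(r_lo = edges[-length(edges)], r_hi = edges[-1],
                r_mid = (edges[-1] + edges[-length(edges)]) / 2,
                count = as.integer(cnt))
  out$probability <- out$count / sum(out$count)
  attr(out, "n") <- length(r)
  attr(out, "peak") <- stats::weighted.mean(out$r_mid, out$probability)
  attr(out, "sd") <- sqrt(stats::weighted.mean(
    (out$r_mid - attr(out, "peak"))^2, out$probability))
  class(out) <- c("radial_histogram", class(out))
  out
}

#' Hydrophobic bond episodes and lifetimes
#'
#' A bond episode is a maximal run of consecutive steps during which a given
#' (binding spot, FG motif) pair satisfies the contact criterion; its
#' lifetime is the run length times the time step (minimum one step =
#' 0.01 ns at the default dt). Accepts either a per-step contact log
#' (columns `step`, `spot`, `motif`) or a `transport_record`, whose
#' engine-recorded episodes are used directly.
#'
#' @param contacts a contact-log tibble or a `transport_record`.
#' @param dt time step in reduced units (0.1 ns each).
#' @return a tibble of episodes (`spot`, `motif`, `start`, `end`,
#'   `lifetime_ns`) with a `summary` attribute
#'   (mean, sd, min, max lifetime in ns).
#' @export
bond_lifetimes <- function(contacts, dt = 1) {
  if (inherits(contacts, "transport_record")) {
    ep <- contacts$episodes
  } else {
    stopifnot(all(c("step", "spot", "motif") %in% names(contacts)))
    ep <- contacts |>
      arrange(.data$spot, .data$motif, .data$step) |>
      group_by(.data$spot, .data$motif) |>
      mutate(run = cumsum(c(1, diff(.data$step) != 1))) |>
      group_by(.data$spot, .data$motif, .data$run) |>
      summarise(start = min(.data$step), end = max(.data$step),
                .groups = "drop") |>
      select(-dplyr::any_of("run")) |>
      mutate(lifetime_ns = (.data$end - .data$start + 1) * dt * 0.1) |>
      arrange(.data$start, .data$spot, .data$motif)
  }
  attr(ep, "summary") <- if (nrow(ep) > 0) {
    list(mean_ns = mean(ep$lifetime_ns), sd_ns = sd(ep$lifetime_ns),
         min_ns = min(ep$lifetime_ns), max_ns = max(ep$lifetime_ns),
         n = nrow(ep))
  } else {
    list(mean_ns = NA_real_, sd_ns = NA_real_, min_ns = NA_real_,
         max_ns = NA_real_, n = 0L)
  }
  ep
}

#' Mean simultaneous binding-spot occupancy
#'
#' The number of binding spots participating in the kap-FG hydrophobic
#' interaction (at least one FG motif inside the 10 nm cutoff), averaged
#' over the engaged steps. The model predicts nearly all eight spots
#' participate at once during transport. Note the distinction from
#' [bond_lifetimes()], whose episodes use the much tighter close-contact
#' radius: participation reproduces the ~7.9-of-8 occupancy statistic,
#' close contacts do not.
#'
#' @param contacts a per-step contact log (columns `step`, `spot`, under
#'   whatever contact criterion produced it) or a `transport_record`
#'   (which uses the engine's exact per-step participation counters).
#' @return mean engaged-spot count over engaged steps.
#' @export
occupancy <- function(contacts) {
  if (inherits(contacts, "transport_record")) {
    if (is.null(contacts$cargo) || !contacts$cargo$active) {
      abort("occupancy is undefined for an inert cargo",
            class = "npcbd_undefined_signal")
    }
    return(contacts$counters$occupancy_mean)
  }
  stopifnot(all(c("step", "spot") %in% names(contacts)))
  if (nrow(contacts) == 0) return(NA_real_)
  per_step <- contacts |>
    group_by(.data$step) |>
    summarise(k = dplyr::n_distinct(.data$spot), .groups = "drop")
  mean(per_step$k)
}

#' Shuttle (back-and-forth) count of a cargo track
#'
#' Counts completed entry -> mid-channel -> entry round trips before the
#' final passage: the cargo crosses the mid-channel plane moving
#' nucleus-ward and later re-emerges past the entry plane on the
#' cytoplasmic side.
#'
#' @param track a cargo track tibble with `y`, or a `transport_record`.
#' @param entry_plane axial coordinate of the channel entry (cytoplasmic
#'   mouth); defaults to the record's `channel_top`.
#' @param mid_plane axial coordinate of the channel midpoint.
#' @return integer round-trip count.
#' @export
shuttle_count <- function(track, entry_plane = NULL, mid_plane = NULL) {
  if (inherits(track, "transport_record")) {
    entry_plane <- entry_plane %||% track$planes$channel_top
    mid_plane <- mid_plane %||% track$planes$mid_channel
    track <- track$track
  }
  stopifnot(!is.null(entry_plane), !is.null(mid_plane),
            mid_plane < entry_plane)
  y <- track$y
  n_trips <- 0L
  reached_mid <- FALSE
  for (v in y) {
    if (!reached_mid && v <= mid_plane) {
      reached_mid <- TRUE
    } else if (reached_mid && v >= entry_plane) {
      n_trips <- n_trips + 1L
      reached_mid <- FALSE
    }
  }
  n_trips
}

#' Percentage of runs that shuttle at least once
#'
#' @param records list of `transport_record`s (e.g. from [run_batch()]).
#' @inheritParams shuttle_count
#' @return percentage (0-100) of records with one or more round trips.
#' @export
shuttle_percentage <- function(records, entry_plane = NULL,
                               mid_plane = NULL) {
  counts <- map_dbl(records, function(r) {
    shuttle_count(r, entry_plane, mid_plane)
  })
  100 * mean(counts >= 1)
}

#' Fraction of the first-passage time spent inside the central channel
#'
#' @param record a completed `transport_record`.
#' @return fraction in `[0, 1]` of the transport window (first filament
#'   contact to basket loading) with the cargo center between the channel
#'   entry and exit planes.
#' @export
channel_residence_fraction <- function(record) {
  stopifnot(inherits(record, "transport_record"))
  ev <- record$events
  if (ev$outcome != "completed" || is.na(ev$t_start_step)) {
    abort("channel residence is defined for completed transports only",
          class = "npcbd_undefined_signal")
  }
  tr <- record$track
  win <- tr$step >= ev$t_start_step & tr$step <= ev$t_end_step
  if (!any(win)) return(NA_real_)
  inside <- tr$y[win] < record$planes$channel_top &
    tr$y[win] > record$planes$channel_bottom
  mean(inside)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
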