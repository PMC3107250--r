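# Shared helpers: small structures, fabricated records, numeric gradients.

default_planes <- function() {
  list(entry = 35, channel_top = 0, mid_channel = -25, channel_bottom = -50,
       basket_top = -50, exit = -125)
}

# A ~50-bead complete pore for force-oracle tests (48 FG motifs).
tiny_npc <- function(seed = 1) {
  build_npc(geometry_config(
    channel_min_diameter = 40, channel_entrance_diameter = 48,
    channel_length = 30, filament_length = 20, basket_length = 40,
    distal_ring_diameter = 28, fg_total_motifs = 48,
    fg_central_contour = 30, fg_peripheral_contour = 90,
    fg_region_weights = c(3, 2, 3), fg_segment_length = 10), seed = seed)
}

# Fabricate a transport_record from a scripted track.
fab_record <- function(y, x = rep(0, length(y)),
                       engaged = rep(0, length(y)),
                       planes = default_planes(), cargo = NULL, dt = 1,
                       events = NULL) {
  step <- seq_along(y) - 1
  track <- tibble::tibble(step = step, x = x, y = y,
                          engaged_spots = engaged,
                          time_ms = steps_to_ms(step, dt), r = abs(x))
  ev <- list(t_start_step = NA_real_, t_end_step = NA_real_,
             t_start_ms = NA_real_, t_end_ms = NA_real_, fpt_ms = NA_real_,
             outcome = "timed_out")
  if (!is.null(events)) ev[names(events)] <- events
  structure(list(
    track = track,
    episodes = tibble::tibble(spot = integer(), motif = integer(),
                              start = double(), end = double(),
                              lifetime_ns = double()),
    contact_log = tibble::tibble(step = double(), spot = integer(),
                                 motif = integer()),
    events = ev,
    counters = list(steps_run = max(step), occupancy_mean = NA_real_,
                    engaged_steps = 0, min_y = min(y), max_wlc_ratio = 0,
                    n_rejected_wlc = 0, n_rejected_wall = 0),
    positions = NULL, planes = planes, cargo = cargo, dt = dt, seed = 0
  ), class = "transport_record")
}

# Central-difference derivative of a scalar function.
num_deriv <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

total_energy_at <- function(structure, positions, cargo = NULL,
                            cargo_position = NULL) {
  sum(total_forces(structure, cargo = cargo,
                   cargo_position = cargo_position,
                   positions = positions)$energy)
}
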