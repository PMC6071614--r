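# Shared fixtures: crafted fish types and worlds for deterministic tests.

# single-state type with explicit urge weights; all other attributes chosen
# small and unremarkable
make_type <- function(name = "probe", wander = 0, rest = 0, cruise = 0,
                      align = 0, centre = 0, spacing = 0,
                      patch_gathering = 0, diver_avoidance = 0,
                      detectability = 1, schooling = FALSE,
                      schooling_distance_bl = 1, patch_distance_m = 0.5,
                      size_m = 0.2, id_distance_m = 4,
                      approach_distance_m = 1,
                      perception_distance_m = if (schooling) 0.35 else NA,
                      perception_angle_deg = 320,
                      max_acceleration_m_s2 = 0.1,
                      max_sustained_speed_m_s = 0.4, burst_speed_m_s = 2.2) {
  fish_type(
    name = name, size_m = size_m, id_distance_m = id_distance_m,
    approach_distance_m = approach_distance_m,
    perception_distance_m = perception_distance_m,
    perception_angle_deg = perception_angle_deg,
    max_acceleration_m_s2 = max_acceleration_m_s2,
    max_sustained_speed_m_s = max_sustained_speed_m_s,
    burst_speed_m_s = burst_speed_m_s,
    states = data.frame(
      state = "only", frequency = 1, detectability = detectability,
      schooling = schooling,
      schooling_distance_bl = schooling_distance_bl,
      patch_distance_m = patch_distance_m,
      align = align, centre = centre, spacing = spacing, wander = wander,
      rest = rest, cruise = cruise, patch_gathering = patch_gathering,
      diver_avoidance = diver_avoidance))
}

# a world whose fish cannot move (all urge weights zero), with fish placed
# exactly where the test wants them
static_world <- function(x, y, type = make_type(), config = world_config(),
                         vx = 0, vy = 0, heading_rad = pi / 2,
                         hidden = FALSE) {
  n <- length(x)
  w <- initialize_world(config, type, seed = 1, burn_in = FALSE)
  w$fish <- list(
    x = as.numeric(x), y = as.numeric(y),
    vx = rep_len(as.numeric(vx), n), vy = rep_len(as.numeric(vy), n),
    hx = rep_len(cos(heading_rad), n), hy = rep_len(sin(heading_rad), n),
    px = as.numeric(x), py = as.numeric(y),
    state = rep(1L, n), hidden = as.integer(rep_len(hidden, n)))
  w$n_fish <- n
  w
}

fish_speeds <- function(world) {
  sqrt(world$fish$vx^2 + world$fish$vy^2)
}
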