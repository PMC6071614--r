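test_that("urge components point where the behaviour says they should", {
  w <- world_config()
  shy <- builtin_fish_types("shy")
  bold <- builtin_fish_types("bold")
  fish <- list(position = c(10, 40), velocity = c(0, 0),
               heading_rad = pi / 2, patch_centre = NULL)

  # all weights zero -> zero steering
  none <- make_type()
  u <- compute_urges(fish, 1, none, diver_pos = c(10, 43))
  expect_equal(as.numeric(u), c(0, 0))

  # shy wandering, diver due north inside id distance: diver component due
  # south, scaled by the ramp between id (6 m) and approach (3 m) distance
  u <- compute_urges(fish, 1, shy, diver_pos = c(10, 44.5))
  comp <- attr(u, "components")$diver_avoidance
  expect_equal(comp, c(0, -(6 - 4.5) / (6 - 3)))
  expect_true(attr(u, "diver_active"))
  # inside the approach distance the flight urge is at full magnitude
  u <- compute_urges(fish, 1, shy, diver_pos = c(10, 42))
  expect_equal(attr(u, "components")$diver_avoidance, c(0, -1))
  # beyond the id distance the diver is ignored
  u <- compute_urges(fish, 1, shy, diver_pos = c(10, 47))
  expect_equal(attr(u, "components")$diver_avoidance, c(0, 0))
  expect_false(attr(u, "diver_active"))

  # bold wandering (negative weight): the weighted diver term points TOWARD
  # the diver; inside the approach distance the attraction switches off
  u <- compute_urges(fish, 1, bold, diver_pos = c(10, 44.5))
  comp <- attr(u, "components")$diver_avoidance
  wterm <- bold$states$diver_avoidance[1] * comp
  expect_lt(comp[2], 0)
  expect_gt(wterm[2], 0)            # net pull northward, toward the diver
  u <- compute_urges(fish, 1, bold, diver_pos = c(10, 42))
  expect_equal(attr(u, "components")$diver_avoidance, c(0, 0))

  # schoolmate urges: alignment follows the mean heading, cohesion points
  # at the centroid, spacing pushes away from too-close neighbours
  sch <- builtin_fish_types("schooling")
  nb <- list(position = rbind(c(10, 40.3), c(10.3, 40)),
             heading_rad = c(0, 0))
  u <- compute_urges(fish, 1, sch, neighbours = nb)
  comp <- attr(u, "components")
  expect_equal(comp$align, c(1, 0))
  expect_equal(comp$centre, c(cos(pi / 4), sin(pi / 4)))
  expect_equal(comp$spacing, c(0, 0))  # both at 0.3 m > 1 BL (0.2 m)
  nb <- list(position = rbind(c(10, 40.1)), heading_rad = pi)
  u <- compute_urges(fish, 1, sch, neighbours = nb)
  expect_equal(attr(u, "components")$spacing, c(0, -1))

  # toroidal metric: a patch centre across the seam pulls the short way
  ty <- make_type(patch_gathering = 5, patch_distance_m = 0.5)
  f2 <- list(position = c(10, 1), velocity = c(0, 0), heading_rad = 0,
             patch_centre = c(10, 79))
  u <- compute_urges(f2, 1, ty, world = w)
  expect_equal(attr(u, "components")$patch_gathering, c(0, -1))
})

test_that("velocity integration obeys drag, acceleration and speed caps", {
  ty <- builtin_fish_types("shy")

  # drag always decelerates a coasting fish
  v1 <- update_velocity(c(0.3, 0.1), c(0, 0), ty)
  expect_lt(sqrt(sum(v1^2)), sqrt(0.3^2 + 0.1^2))

  # constant cruise urge from rest: speed rises monotonically and plateaus
  # at the sustained cap (0.4 m/s for this type)
  v <- c(0, 0)
  speeds <- numeric(300)
  for (i in 1:300) {
    v <- update_velocity(v, c(10, 0), ty)   # cruise weight 10, due east
    speeds[i] <- sqrt(sum(v^2))
  }
  expect_true(all(diff(speeds) > -1e-12))
  expect_equal(speeds[300], ty$max_sustained_speed_m_s, tolerance = 1e-9)

  # random steering never beats the caps, burst or sustained
  set.seed(7)
  for (i in 1:2000) {
    v <- runif(2, -3, 3)
    u <- runif(2, -30, 30)
    expect_lte(sqrt(sum(update_velocity(v, u, ty, FALSE)^2)),
               ty$max_sustained_speed_m_s + 1e-12)
    expect_lte(sqrt(sum(update_velocity(v, u, ty, TRUE)^2)),
               ty$burst_speed_m_s + 1e-12)
  }
})

test_that("state re-picks follow the repertoire frequencies", {
  # single-state repertoire: the state never changes, hidden is still
  # redrawn from its detectability
  one <- make_type(detectability = 0.4)
  set.seed(1)
  draws <- maybe_switch_state(one, 20000)
  expect_true(all(draws$state == 1L))
  expect_equal(mean(draws$hidden), 1 - 0.4, tolerance = 0.02)

  # full-detectability states can never hide a fish
  sure <- make_type(detectability = 1)
  set.seed(2)
  expect_false(any(maybe_switch_state(sure, 5000)$hidden))

  # cryptic repertoire: empirical pick frequencies within 3 binomial
  # standard errors of the nominal {0.25, 0.2, 0.1, 0.45}
  cry <- builtin_fish_types("cryptic")
  set.seed(3)
  n <- 1e5
  draws <- maybe_switch_state(cry, n)
  p <- cry$states$frequency
  for (s in seq_along(p)) {
    phat <- mean(draws$state == s)
    expect_lt(abs(phat - p[s]), 3 * sqrt(p[s] * (1 - p[s]) / n))
  }

  # nested blennies (detectability 0.1) are visible in ~10% of draws
  nested <- draws$state == 3L
  expect_equal(mean(!draws$hidden[nested]), 0.1, tolerance = 0.1)

  # schooling states all have detectability 1: always visible
  sch <- builtin_fish_types("schooling")
  set.seed(4)
  expect_false(any(maybe_switch_state(sch, 5000)$hidden))
  expect_true(all(is_visible(list(hidden = rep(FALSE, 3)))))
})

test_that("the engine tick reproduces the reference urge and velocity rules", {
  cfg <- world_config()
  # deterministic steering (wander weight 0): cruise + rest + diver flight
  ty <- make_type(cruise = 10, rest = 2, diver_avoidance = 10,
                  id_distance_m = 6, approach_distance_m = 3)
  x <- c(4, 10, 16)
  y <- c(30, 41, 70)
  w <- static_world(x, y, type = ty, config = cfg,
                    vx = 0.2, vy = 0.1, heading_rad = 0.3)
  sv <- survey_config("point", radius_m = 4, time_min = 1,
                      rotation_deg_s = 6)
  w <- place_diver(w, sv)      # diver at (10, 40)
  stepped <- step_movement(w)
  for (i in seq_along(x)) {
    fish <- list(position = c(x[i], y[i]), velocity = c(0.2, 0.1),
                 heading_rad = 0.3, patch_centre = c(x[i], y[i]))
    u <- compute_urges(fish, 1, ty, diver_pos = c(10, 40), world = cfg)
    v2 <- update_velocity(c(0.2, 0.1), as.numeric(u), ty,
                          diver_active = attr(u, "diver_active"))
    expect_equal(stepped$fish$vx[i], v2[1], tolerance = 1e-12)
    expect_equal(stepped$fish$vy[i], v2[2], tolerance = 1e-12)
    expect_equal(stepped$fish$x[i], (x[i] + v2[1] * 0.1) %% 20,
                 tolerance = 1e-12)
  }

  # stochastic steering: the engine draws one wander deviation per fish per
  # tick, in fish order, from R's RNG
  ty <- make_type(wander = 5)
  w <- static_world(x, y, type = ty, config = cfg, heading_rad = 1.1)
  set.seed(99)
  stepped <- step_movement(w)
  set.seed(99)
  devs <- runif(3, -30, 30)
  for (i in seq_along(x)) {
    fish <- list(position = c(x[i], y[i]), velocity = c(0, 0),
                 heading_rad = 1.1, patch_centre = NULL)
    u <- compute_urges(fish, 1, ty, wander_dev_deg = devs[i], world = cfg)
    v2 <- update_velocity(c(0, 0), as.numeric(u), ty)
    expect_equal(stepped$fish$vx[i], v2[1], tolerance = 1e-12)
    expect_equal(stepped$fish$vy[i], v2[2], tolerance = 1e-12)
  }

  # schooling urges: engine neighbour search matches the reference with a
  # hand-picked neighbour set (perception radius 0.35 m, 320 degree cone)
  sch <- make_type(align = 5, centre = 6, spacing = 15, schooling = TRUE,
                   perception_distance_m = 0.35, max_acceleration_m_s2 = 0.2,
                   max_sustained_speed_m_s = 0.5, burst_speed_m_s = 2.6)
  pos <- rbind(c(10, 40), c(10, 40.3), c(10.2, 39.9), c(12, 40), c(10, 39.62))
  # fish 4 out of range; fish 5 is 0.38 m away (out of range); fish 2 and 3
  # are in range and inside the cone of fish 1 (heading north)
  w <- static_world(pos[, 1], pos[, 2], type = sch, config = cfg,
                    heading_rad = pi / 2)
  set.seed(5)
  stepped <- step_movement(w)
  set.seed(5)
  devs <- runif(5, -30, 30)
  fish1 <- list(position = pos[1, ], velocity = c(0, 0),
                heading_rad = pi / 2, patch_centre = NULL)
  nb <- list(position = pos[2:3, ], heading_rad = rep(pi / 2, 2))
  u <- compute_urges(fish1, 1, sch, neighbours = nb,
                     wander_dev_deg = devs[1], world = cfg)
  v2 <- update_velocity(c(0, 0), as.numeric(u), sch)
  expect_equal(stepped$fish$vx[1], v2[1], tolerance = 1e-12)
  expect_equal(stepped$fish$vy[1], v2[2], tolerance = 1e-12)
})

test_that("speed caps hold over long random engine runs", {
  cfg <- world_config(true_density = 0.05)   # 80 fish
  for (nm in c("shy", "schooling")) {
    ty <- builtin_fish_types(nm)
    w <- initialize_world(cfg, ty, seed = 11)
    sv <- survey_config("point", radius_m = 5, time_min = 2,
                        rotation_deg_s = 6)
    w <- place_diver(w, sv)
    burst <- ty$burst_speed_m_s
    for (i in 1:30) {
      for (t in 1:10) w <- step_movement(w)
      w <- step_second(w)
      expect_true(all(fish_speeds(w) <= burst + 1e-9))
    }
  }
})
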