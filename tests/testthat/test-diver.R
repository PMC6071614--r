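test_that("diver movement follows protocol kinematics", {
  w <- static_world(10, 40)
  tr <- place_diver(w, survey_config("transect", length_m = 30, width_m = 4,
                                     speed_m_min = 6))$diver
  y0 <- tr$y
  for (t in 1:10) tr <- move_diver(tr)
  expect_equal(tr$y - y0, 0.1)          # 6 m/min for one second
  expect_equal(tr$dist, 0.1)

  pt <- place_diver(w, survey_config("point", radius_m = 4, time_min = 3,
                                     rotation_deg_s = 10))$diver
  h0 <- pt$heading
  for (t in 1:360) pt <- move_diver(pt)  # 36 s at 10 deg/s
  expect_equal(h0 - pt$heading, 2 * pi)  # one full clockwise turn
  expect_equal(pt$x, 10)                 # position fixed

  # Table-like bounds: 2 deg/s over 3 min is one turn, over 11 min is 1320
  expect_equal(2 * 3 * 60, 360)
  expect_equal(2 * 11 * 60, 1320)
})

test_that("visibility requires range, cone, sample limits and detectability", {
  sv <- survey_config("transect", length_m = 40, width_m = 4,
                      speed_m_min = 6)
  # diver at (10, 20) heading north; strip x in [8, 12], y in [20, 60]
  mkw <- function(x, y, hidden = FALSE) {
    w <- static_world(x, y, hidden = hidden)
    place_diver(w, sv)
  }
  # fish 7 m dead ahead: inside the strip but beyond 6 m visibility
  expect_equal(nrow(visible_fish(mkw(10, 27))), 0)
  # fish 5 m dead ahead: visible
  expect_equal(nrow(visible_fish(mkw(10, 25))), 1)
  # fish inside the strip but behind the diver's view cone: not countable
  # until the cone sweeps it
  w <- mkw(10, 29)
  w$diver$y <- 30                       # diver has advanced into the strip
  expect_equal(nrow(visible_fish(w)), 0)
  w$diver$y <- 28                       # same fish, now ahead
  expect_equal(nrow(visible_fish(w)), 1)
  # fish outside the strip width, in range and cone
  expect_equal(nrow(visible_fish(mkw(13, 22))), 0)
  # hidden fish dead ahead at 1 m
  expect_equal(nrow(visible_fish(mkw(10, 21, hidden = TRUE))), 0)
  # ordering: closest first
  w <- mkw(c(10, 10.5, 9.5), c(24, 21, 22.5))
  vf <- visible_fish(w)
  expect_equal(vf$index, c(2L, 3L, 1L))
  expect_equal(vf$distance, sort(vf$distance))
})

test_that("counting saturates at three fish per second, closest first", {
  sv <- survey_config("point", radius_m = 5, time_min = 3,
                      rotation_deg_s = 0, view_angle_deg = 360)
  # five fish at staggered distances north of the diver at (10, 40)
  w <- static_world(rep(10, 5), 40 + c(1, 2, 3, 4, 4.5))
  w <- place_diver(w, sv)
  w <- count_visible(w)
  expect_equal(w$diver$count, 3L)
  expect_equal(which(w$diver$mem == 1L), 1:3)  # the three nearest
  w <- count_visible(w)
  expect_equal(w$diver$count, 5L)              # the remaining two
  w <- count_visible(w)
  expect_equal(w$diver$count, 5L)              # everyone remembered
})

test_that("count memory forgets only when a fish leaves the field", {
  sv <- survey_config("point", radius_m = 5, time_min = 3,
                      rotation_deg_s = 0, view_angle_deg = 360)
  w <- static_world(10, 43)
  w <- place_diver(w, sv)
  # continuously visible fish is counted exactly once, however long it stays
  for (i in 1:10) w <- count_visible(w)
  expect_equal(w$diver$count, 1L)

  # leaving the sampling unit but staying within visibility: still
  # remembered under the default rule, so not recounted on return
  w$fish$y <- 45.5                      # 5.5 m: outside r=5, inside 6 m
  w <- count_visible(w)
  w$fish$y <- 43
  w <- count_visible(w)
  expect_equal(w$diver$count, 1L)

  # leaving the visibility range resets the memory: one extra count per
  # re-entry
  w$fish$y <- 47                        # 7 m away
  w <- count_visible(w)
  w$fish$y <- 43
  w <- count_visible(w)
  expect_equal(w$diver$count, 2L)

  # under the strict field-of-view rule, merely leaving the view cone makes
  # the fish recountable (a rotating diver recounts on every pass)
  svf <- survey_config("point", radius_m = 5, time_min = 3,
                       rotation_deg_s = 0, view_angle_deg = 160,
                       memory = "fov")
  w <- static_world(10, 43)
  w <- place_diver(w, svf)
  w <- count_visible(w)
  expect_equal(w$diver$count, 1L)
  w$diver$heading <- -pi / 2            # look south: fish leaves the cone
  w <- count_visible(w)
  w$diver$heading <- pi / 2
  w <- count_visible(w)
  expect_equal(w$diver$count, 2L)
})

test_that("density is count over area", {
  expect_equal(estimate_density(
    75, survey_config("transect", length_m = 50, width_m = 5,
                      speed_m_min = 6)), 0.3)
  expect_equal(estimate_density(
    0, survey_config("point", radius_m = 2, time_min = 3,
                     rotation_deg_s = 2)), 0)
  expect_equal(estimate_density(
    40, survey_config("point", radius_m = 5, time_min = 3,
                      rotation_deg_s = 2)), 40 / (25 * pi))
  expect_error(survey_config("transect", length_m = 0, width_m = 5,
                             speed_m_min = 6), "positive")
})

test_that("a static always-visible world is surveyed without bias", {
  # immobile, fully detectable fish, 360-degree view, protocols that sweep
  # the whole unit: everything inside is counted exactly once, so the only
  # deviation from Dt is sampling noise in who starts inside the unit
  ty <- make_type(detectability = 1)
  cfg <- world_config()
  sv <- survey_config("point", radius_m = 5, time_min = 2,
                      rotation_deg_s = 4, view_angle_deg = 360)
  de <- vapply(1:60, function(s) {
    run_survey(cfg, ty, sv, seed = 2000 + s)$density
  }, numeric(1))
  se <- sd(de) / sqrt(length(de))
  expect_lt(abs(mean(de) - 0.3), 3 * se)
  # and each replicate equals its own snapshot census exactly
  w <- initialize_world(cfg, ty, seed = 2001)
  expect_equal(run_survey(cfg, ty, sv, seed = 2001)$density,
               snapshot_density(w, sv))
})
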