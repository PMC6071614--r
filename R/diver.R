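#' Survey configuration
#'
#' Defines one of the two census protocols.  A strip transect diver swims
#' forward along the arena's long axis at a fixed speed, counting within a
#' strip of fixed width between the transect's start and end lines; the
#' survey ends when the transect length has been covered.  A stationary
#' point-count diver rotates clockwise on a fixed point, counting within a
#' fixed radius for a fixed time.
#'
#' @param protocol `"transect"` or `"point"`.
#' @param length_m,width_m,speed_m_min transect length (m), strip width (m)
#'   and swim speed (m/min).
#' @param radius_m,time_min,rotation_deg_s point-count radius (m), survey
#'   duration (min) and clockwise rotation speed (degrees/s).
#' @param view_angle_deg the diver's field of view in degrees, centred on
#'   the current heading (default 160, a typical human field of view with a
#'   dive mask).
#' @param memory the diver's forgetting rule for counted fish.  With
#'   `"unit"` (the default) a counted fish is remembered — and so not
#'   recounted — for as long as it stays inside the sampling-unit limits
#'   and visibility range, and is forgotten (recountable) once it leaves
#'   and re-enters the sample.  With `"fov"` a counted fish is forgotten as
#'   soon as it drops out of the instantaneous field of view (view cone,
#'   range, unit limits or a failed detectability redraw), so a rotating
#'   point-count diver recounts stationary fish on every pass.  See the
#'   methods vignette for why `"unit"` is the default.
#' @return an object of class `fc_survey_config`.
#' @export
survey_config <- function(protocol = c("transect", "point"),
                          length_m = NULL, width_m = NULL,
                          speed_m_min = NULL, radius_m = NULL,
                          time_min = NULL, rotation_deg_s = NULL,
                          view_angle_deg = 160,
                          memory = c("visibility", "unit", "fov")) {
  protocol <- match.arg(protocol)
  memory <- match.arg(memory)
  if (!is.finite(view_angle_deg) || view_angle_deg <= 0 ||
      view_angle_deg > 360)
    stop("view angle must be in (0, 360]")
  if (protocol == "transect") {
    if (is.null(length_m) || is.null(width_m) || is.null(speed_m_min))
      stop("transect needs length_m, width_m and speed_m_min")
    if (length_m <= 0 || width_m <= 0 || speed_m_min <= 0)
      stop("transect dimensions and speed must be positive")
    params <- list(length_m = length_m, width_m = width_m,
                   speed_m_min = speed_m_min)
  } else {
    if (is.null(radius_m) || is.null(time_min) || is.null(rotation_deg_s))
      stop("point count needs radius_m, time_min and rotation_deg_s")
    if (radius_m <= 0 || time_min <= 0 || rotation_deg_s < 0)
      stop("point-count radius and time must be positive")
    params <- list(radius_m = radius_m, time_min = time_min,
                   rotation_deg_s = rotation_deg_s)
  }
  structure(list(protocol = protocol, params = params,
                 view_angle_deg = view_angle_deg, memory = memory),
            class = "fc_survey_config")
}

#' Sample area of a survey configuration
#'
#' Transects: `length_m * width_m`.  Point counts: `pi * radius_m^2`.
#'
#' @param survey an [survey_config()].
#' @return area in m^2.
#' @export
survey_area_m2 <- function(survey) {
  stopifnot(inherits(survey, "fc_survey_config"))
  if (survey$protocol == "transect")
    survey$params$length_m * survey$params$width_m
  else
    pi * survey$params$radius_m^2
}

survey_duration_s <- function(survey) {
  if (survey$protocol == "transect")
    60 * survey$params$length_m / survey$params$speed_m_min
  else
    60 * survey$params$time_min
}

#' Place a diver in a world
#'
#' The transect diver starts on the long-axis midline, with the strip
#' centred along the long axis so that the sampling unit plus a
#' visibility-wide buffer fits inside the arena; it fails with a
#' configuration error when the transect is too long for the available
#' runway.  The point-count diver sits at the arena centre; its radius may
#' not exceed the visibility limit.  The diver itself never wraps around
#' the edges.
#'
#' @param world an `fc_world` without a diver.
#' @param survey an [survey_config()].
#' @return the world with the diver placed.
#' @export
place_diver <- function(world, survey) {
  stopifnot(inherits(world, "fc_world"),
            inherits(survey, "fc_survey_config"))
  cfg <- world$config
  n <- world$n_fish
  view_half_cos <- cos(survey$view_angle_deg * pi / 360)
  if (survey$protocol == "transect") {
    len <- survey$params$length_m
    if (len + 2 * cfg$visibility_m > cfg$height_m)
      stop("transect of ", len, " m does not fit in a ", cfg$height_m,
           " m arena with a ", cfg$visibility_m, " m buffer at each end")
    y0 <- (cfg$height_m - len) / 2
    diver <- list(
      protocol = 0L, x = cfg$width_m / 2, y = y0, heading = pi / 2,
      speed_mps = survey$params$speed_m_min / 60, rot_rad_ps = 0,
      half_width = survey$params$width_m / 2, y0 = y0, y1 = y0 + len,
      radius = 0, cos_view_half = view_half_cos,
      mem_rule = switch(survey$memory, unit = 0L, fov = 1L,
                        visibility = 2L),
      mem = integer(n), count = 0L, dist = 0)
  } else {
    if (survey$params$radius_m > cfg$visibility_m)
      stop("point-count radius exceeds the visibility limit (",
           cfg$visibility_m, " m)")
    diver <- list(
      protocol = 1L, x = cfg$width_m / 2, y = cfg$height_m / 2,
      heading = pi / 2, speed_mps = 0,
      rot_rad_ps = survey$params$rotation_deg_s * pi / 180,
      half_width = 0, y0 = 0, y1 = 0,
      radius = survey$params$radius_m, cos_view_half = view_half_cos,
      mem_rule = switch(survey$memory, unit = 0L, fov = 1L,
                        visibility = 2L),
      mem = integer(n), count = 0L, dist = 0)
  }
  world$diver <- diver
  world
}

#' Move the diver by one 0.1 s tick
#'
#' Reference implementation of the diver movement rule: a transect diver
#' advances `speed * dt` along its fixed heading, a point-count diver
#' rotates clockwise by `rotation * dt` while its position stays fixed.
#' The simulation engine applies the same rule inside [step_movement()].
#'
#' @param diver a diver as stored in `world$diver`.
#' @param dt time step in seconds (default 0.1).
#' @return the moved diver.
#' @export
move_diver <- function(diver, dt = 0.1) {
  if (diver$protocol == 0L) {
    diver$y <- diver$y + diver$speed_mps * dt
    diver$dist <- diver$dist + diver$speed_mps * dt
  } else {
    diver$heading <- diver$heading - diver$rot_rad_ps * dt
  }
  diver
}

#' Fish currently visible to the diver
#'
#' A fish is visible when all of the following hold: it is not hidden (its
#' detectability Bernoulli draw), it lies within the visibility range, it
#' falls inside the diver's view cone about the current heading, and it is
#' inside the sampling-unit limits (the full strip between the transect's
#' start and end lines, or the point-count radius).  Results are ordered by
#' increasing distance: the diver prioritises the closest fish.
#'
#' @param world an `fc_world` with a placed diver.
#' @return a data frame with columns `index` (fish index) and `distance`
#'   (m), sorted by distance.
#' @export
visible_fish <- function(world) {
  stopifnot(inherits(world, "fc_world"))
  if (is.null(world$diver)) stop("no diver placed")
  res <- eng_visible(world$fish, world$diver, wcfg_engine(world$config))
  data.frame(index = res$index, distance = res$distance)
}

#' Count visible fish (one-second counting step)
#'
#' The per-second counting rule: remembered fish that are no longer in the
#' current visible set are forgotten (and so can be recounted if they
#' re-enter the field of view); then up to three of the closest visible,
#' not-yet-remembered fish are added to the tally — the saturation limit of
#' three fish per second.
#'
#' @param world an `fc_world` with a placed diver.
#' @return the world with the diver's count and memory updated.
#' @export
count_visible <- function(world) {
  stopifnot(inherits(world, "fc_world"))
  if (is.null(world$diver)) stop("no diver placed")
  world$diver <- eng_count(world$fish, world$diver,
                           wcfg_engine(world$config))
  world
}

#' Density estimate from a finished survey
#'
#' De = count / sample area.
#'
#' @param count total fish counted.
#' @param survey the [survey_config()] that produced the count.
#' @return estimated density in fish/m^2.
#' @export
estimate_density <- function(count, survey) {
  area <- survey_area_m2(survey)
  if (area <= 0) stop("sample area must be positive")
  count / area
}
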