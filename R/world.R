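#' World configuration
#'
#' The simulated seascape: a two-dimensional toroidal rectangle (fish wrap
#' around the edges; the diver does not) with a fixed horizontal visibility
#' and a fixed true fish density.  Defaults follow the reference setup:
#' a 20 x 80 m (1,600 m^2) arena, 6 m visibility and a true density of
#' 0.3 fish/m^2.
#'
#' @param width_m,height_m arena dimensions in metres.  Transects run along
#'   the `height_m` (long) axis.
#' @param visibility_m maximum horizontal visibility in metres; constant
#'   within a run.
#' @param true_density true fish density Dt in fish/m^2.  The number of
#'   simulated fish is `round(true_density * width_m * height_m)` and is
#'   constant for a whole run.
#' @return an object of class `fc_world_config`.
#' @export
world_config <- function(width_m = 20, height_m = 80, visibility_m = 6,
                         true_density = 0.3) {
  if (!is.finite(width_m) || width_m <= 0 ||
      !is.finite(height_m) || height_m <= 0)
    stop("world dimensions must be positive")
  if (!is.finite(visibility_m) || visibility_m <= 0)
    stop("visibility must be positive")
  if (!is.finite(true_density) || true_density <= 0)
    stop("true density must be positive (no fish to survey otherwise)")
  structure(
    list(width_m = width_m, height_m = height_m,
         visibility_m = visibility_m, true_density = true_density),
    class = "fc_world_config")
}

wcfg_engine <- function(cfg) {
  list(width = cfg$width_m, height = cfg$height_m,
       visibility = cfg$visibility_m)
}

#' Initialise a world
#'
#' Places `round(Dt * area)` fish uniformly at random with uniform random
#' headings and zero velocity, assigns every fish the first behavioural
#' state of the repertoire (drawing its hidden flag from that state's
#' detectability) and anchors each fish's patch centre at its start
#' location.  By default the movement submodel is then run for 200 cycles
#' (20 model seconds) of burn-in, which stabilises positions and lets
#' schools form before a diver is placed; the every-10-second behavioural
#' re-pick runs during burn-in, the diver-related procedures do not.
#'
#' @param config an [world_config()] object.
#' @param type an [fish_type()] object.
#' @param seed optional integer seed; identical seeds give bit-identical
#'   worlds.
#' @param burn_in logical; run the 200-cycle burn-in (default `TRUE`).
#' @return an object of class `fc_world`.
#' @export
initialize_world <- function(config, type, seed = NULL, burn_in = TRUE) {
  stopifnot(inherits(config, "fc_world_config"),
            inherits(type, "fc_fish_type"))
  validate_fish_type(type)
  if (!is.null(seed)) set.seed(seed)
  n <- round(config$true_density * config$width_m * config$height_m)
  if (n < 1) stop("true density too low: no fish to simulate")
  x <- runif(n, 0, config$width_m)
  y <- runif(n, 0, config$height_m)
  heading <- runif(n, 0, 360) * pi / 180
  detect1 <- type$states$detectability[1]
  hidden <- as.integer(runif(n) > detect1)
  fish <- list(
    x = x, y = y, vx = numeric(n), vy = numeric(n),
    hx = cos(heading), hy = sin(heading),
    px = x, py = y,
    state = rep(1L, n), hidden = hidden)
  world <- structure(
    list(config = config, type = type, fish = fish, diver = NULL,
         clock_s = 0L, n_fish = n),
    class = "fc_world")
  if (burn_in) {
    res <- eng_run(world$fish, ft_engine(type), NULL, wcfg_engine(config),
                   20L, 0L)
    world$fish <- res$fish
    world$clock_s <- res$clock
  }
  world
}

#' @export
print.fc_world <- function(x, ...) {
  cat(sprintf(
    "<fc_world> %g x %g m | visibility %g m | Dt %g fish/m^2 | %d fish\n",
    x$config$width_m, x$config$height_m, x$config$visibility_m,
    x$config$true_density, x$n_fish))
  cat(sprintf("  type: %s | clock %d s | diver %s\n", x$type$name,
              x$clock_s,
              if (is.null(x$diver)) "absent" else
                c("transect", "point")[x$diver$protocol + 1L]))
  invisible(x)
}

#' Advance the world by one movement tick (0.1 s)
#'
#' All fish compute their steering urges from the pre-step configuration
#' and then move simultaneously (synchronous update); the diver, if placed,
#' advances by the same 0.1 s.  Movement ticks do not run the once-per-
#' second procedures; see [step_second()].
#'
#' @param world an `fc_world`.
#' @return the advanced world.
#' @export
step_movement <- function(world) {
  stopifnot(inherits(world, "fc_world"))
  res <- eng_move(world$fish, ft_engine(world$type), world$diver,
                  wcfg_engine(world$config), 1L)
  world$fish <- res$fish
  world$diver <- res$diver
  world
}

#' Run the once-per-second model procedures
#'
#' Called after ten movement ticks: advances the model clock by one second,
#' lets the diver (if placed) count visible fish, and at clock values
#' divisible by ten lets every fish re-pick its behavioural state by a
#' frequency-weighted draw with replacement, redrawing its hidden flag from
#' the new state's detectability.
#'
#' @param world an `fc_world`.
#' @return the advanced world.
#' @export
step_second <- function(world) {
  stopifnot(inherits(world, "fc_world"))
  world$clock_s <- world$clock_s + 1L
  if (!is.null(world$diver))
    world$diver <- eng_count(world$fish, world$diver,
                             wcfg_engine(world$config))
  if (world$clock_s %% 10L == 0L)
    world$fish <- eng_switch(world$fish, ft_engine(world$type))
  world
}

#' Run one complete survey replicate
#'
#' Initialises the world from `seed` (fresh random fish locations every
#' replicate), runs the 200-cycle burn-in, places the diver, loops the
#' two-level scheduler until the protocol's end condition (transect:
#' distance covered equals the transect length; point count: elapsed time
#' equals the survey time), and estimates density by dividing the final
#' count by the sample area.
#'
#' @param config an [world_config()].
#' @param type an [fish_type()].
#' @param survey an [survey_config()].
#' @param seed integer seed for the replicate.
#' @return an object of class `fc_survey_result`: a list with `count`,
#'   `area_m2`, `density` (the estimate De), `true_density`, `trait`,
#'   `protocol`, the survey parameters and `seed`.
#' @export
run_survey <- function(config, type, survey, seed) {
  stopifnot(inherits(survey, "fc_survey_config"))
  world <- initialize_world(config, type, seed = seed, burn_in = TRUE)
  world <- place_diver(world, survey)
  dur <- survey_duration_s(survey)
  nsec <- floor(dur + 1e-9)
  res <- eng_run(world$fish, ft_engine(type), world$diver,
                 wcfg_engine(config), as.integer(nsec), world$clock_s)
  world$fish <- res$fish
  world$diver <- res$diver
  world$clock_s <- res$clock
  rem_ticks <- ceiling((dur - nsec) * 10 - 1e-9)
  if (rem_ticks > 0) {
    mv <- eng_move(world$fish, ft_engine(type), world$diver,
                   wcfg_engine(config), as.integer(rem_ticks))
    world$fish <- mv$fish
    world$diver <- mv$diver
  }
  count <- world$diver$count
  area <- survey_area_m2(survey)
  structure(
    list(count = count, area_m2 = area, density = count / area,
         true_density = config$true_density, trait = type$name,
         protocol = survey$protocol, params = survey$params, seed = seed),
    class = "fc_survey_result")
}

#' @export
print.fc_survey_result <- function(x, ...) {
  cat(sprintf(
    "<fc_survey_result> %s | %s | count %d | area %.1f m^2 | De %.4f (Dt %.4f)\n",
    x$trait, x$protocol, x$count, x$area_m2, x$density, x$true_density))
  invisible(x)
}

#' @export
as.data.frame.fc_survey_result <- function(x, ...) {
  cbind(
    data.frame(trait = x$trait, protocol = x$protocol,
               stringsAsFactors = FALSE),
    as.data.frame(x$params),
    data.frame(seed = x$seed, count = x$count, area_m2 = x$area_m2,
               density = x$density, true_density = x$true_density))
}

#' Instantaneous snapshot census
#'
#' The idealised census the survey protocols are judged against: every fish
#' inside the sampling-unit footprint at a single instant is counted,
#' regardless of detectability or view direction, and the count is divided
#' by the unit area.  Over many seeds its mean matches the true density up
#' to binomial sampling error only, so any systematic deviation of a
#' simulated survey from Dt is attributable to movement, behaviour and
#' survey geometry.
#'
#' @param world an `fc_world` (typically fresh from [initialize_world()]).
#' @param survey an [survey_config()] giving the unit footprint.
#' @return snapshot density estimate in fish/m^2.
#' @export
snapshot_density <- function(world, survey) {
  stopifnot(inherits(world, "fc_world"),
            inherits(survey, "fc_survey_config"))
  cfg <- world$config
  fx <- world$fish$x
  fy <- world$fish$y
  if (survey$protocol == "transect") {
    hw <- survey$params$width_m / 2
    cx <- cfg$width_m / 2
    y0 <- (cfg$height_m - survey$params$length_m) / 2
    y1 <- y0 + survey$params$length_m
    inside <- abs(fx - cx) <= hw & fy >= y0 & fy <= y1
  } else {
    r <- survey$params$radius_m
    inside <- (fx - cfg$width_m / 2)^2 + (fy - cfg$height_m / 2)^2 <= r^2
  }
  sum(inside) / survey_area_m2(survey)
}
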