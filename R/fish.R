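#' Steering urges for one fish
#'
#' Reference implementation of the urge-vector steering rule.  Each active
#' urge contributes a direction vector of magnitude at most one, scaled by
#' the state's signed weight, and the returned steering vector is the
#' weighted sum (clipping to the maximum acceleration happens later, in
#' [update_velocity()]):
#'
#' * `align` — unit mean heading of the perceived schoolmates;
#' * `centre` — unit vector toward their centroid;
#' * `spacing` — sum of unit vectors away from schoolmates closer than
#'   the schooling distance, norm-clamped at one;
#' * `wander` — unit vector along the current heading rotated by the
#'   supplied deviation (drawn uniformly on ±30 degrees each tick in the
#'   simulation);
#' * `rest` — unit vector opposing the current velocity (zero at rest);
#' * `cruise` — unit vector along the current heading;
#' * `patch_gathering` — unit vector toward the fish's patch centre, active
#'   only beyond the state's patch distance;
#' * `diver_avoidance` — unit vector away from the diver, ramping from zero
#'   at the identification distance to full magnitude at the approach
#'   distance; a negative weight turns it into attraction, which switches
#'   off inside the approach distance (the fish holds its standoff).
#'
#' Schoolmate perception (distance and cone filtering) is the caller's
#' responsibility: `neighbours` are the already-perceived schoolmates.
#' Distances to neighbours, the patch centre and the diver use the shortest
#' toroidal (minimum-image) separation.
#'
#' @param fish list with `position` (x, y), `velocity` (vx, vy),
#'   `heading_rad` and optionally `patch_centre` (x, y).
#' @param state a single row of `type$states` (or the index of one).
#' @param type the [fish_type()].
#' @param neighbours `NULL`, or a list with `position` (k x 2 matrix) and
#'   `heading_rad` (length-k vector) of perceived schoolmates.
#' @param diver_pos `NULL`, or the diver position (x, y).
#' @param wander_dev_deg wander deviation in degrees for this tick.
#' @param world an [world_config()] supplying the toroidal dimensions.
#' @return the steering vector (length-2 numeric, m/s^2 scale), with the
#'   unweighted unit contributions attached as attribute `"components"` and
#'   the burst-permission flag as attribute `"diver_active"`.
#' @export
compute_urges <- function(fish, state, type, neighbours = NULL,
                          diver_pos = NULL, wander_dev_deg = 0,
                          world = world_config()) {
  if (!is.data.frame(state)) state <- type$states[state, , drop = FALSE]
  W <- world$width_m
  H <- world$height_m
  mimg <- function(d, L) d - L * round(d / L)
  unit <- function(v) {
    n <- sqrt(sum(v^2))
    if (n > 1e-9) v / n else c(0, 0)
  }
  comp <- list(align = c(0, 0), centre = c(0, 0), spacing = c(0, 0),
               wander = c(0, 0), rest = c(0, 0), cruise = c(0, 0),
               patch_gathering = c(0, 0), diver_avoidance = c(0, 0))
  h <- c(cos(fish$heading_rad), sin(fish$heading_rad))

  if (!is.null(neighbours) && NROW(neighbours$position) > 0 &&
      isTRUE(as.logical(state$schooling))) {
    off <- cbind(mimg(neighbours$position[, 1] - fish$position[1], W),
                 mimg(neighbours$position[, 2] - fish$position[2], H))
    d <- sqrt(rowSums(off^2))
    comp$align <- unit(c(sum(cos(neighbours$heading_rad)),
                         sum(sin(neighbours$heading_rad))))
    comp$centre <- unit(colSums(off))
    close <- d < state$schooling_distance_bl * type$size_m & d > 1e-9
    if (any(close)) {
      sp <- -colSums(off[close, , drop = FALSE] / d[close])
      n <- sqrt(sum(sp^2))
      comp$spacing <- if (n > 1) sp / n else sp
    }
  }
  if (state$wander != 0) {
    dev <- wander_dev_deg * pi / 180
    rot <- matrix(c(cos(dev), sin(dev), -sin(dev), cos(dev)), 2, 2)
    comp$wander <- as.numeric(rot %*% h)
  }
  spd <- sqrt(sum(fish$velocity^2))
  if (state$rest != 0 && spd > 1e-9)
    comp$rest <- -fish$velocity / spd
  if (state$cruise != 0)
    comp$cruise <- h
  if (state$patch_gathering != 0 && !is.null(fish$patch_centre)) {
    off <- c(mimg(fish$patch_centre[1] - fish$position[1], W),
             mimg(fish$patch_centre[2] - fish$position[2], H))
    d <- sqrt(sum(off^2))
    if (d > state$patch_distance_m && d > 1e-9)
      comp$patch_gathering <- off / d
  }
  diver_active <- FALSE
  if (!is.null(diver_pos) && state$diver_avoidance != 0) {
    off <- c(mimg(fish$position[1] - diver_pos[1], W),
             mimg(fish$position[2] - diver_pos[2], H))
    d <- sqrt(sum(off^2))
    if (d < type$id_distance_m) {
      diver_active <- TRUE
      mag <- if (d <= type$approach_distance_m) {
        if (state$diver_avoidance > 0) 1 else 0
      } else {
        (type$id_distance_m - d) /
          (type$id_distance_m - type$approach_distance_m)
      }
      if (mag > 0 && d > 1e-9)
        comp$diver_avoidance <- mag * off / d
    }
  }
  w <- c(state$align, state$centre, state$spacing, state$wander,
         state$rest, state$cruise, state$patch_gathering,
         state$diver_avoidance)
  total <- colSums(do.call(rbind, comp) * w)
  structure(total, components = comp, diver_active = diver_active)
}

#' Velocity update with drag and speed caps
#'
#' Reference implementation of the drag-limited velocity integration:
#' the steering vector is clipped to the maximum acceleration, quadratic
#' friction drag (`drag_constant * |v| * v`) decelerates the fish, and the
#' new speed is capped at the sustained speed — or the burst speed while
#' the diver-reaction urge is active (flight or approach response).
#'
#' `v' = clip_speed( v (1 - k |v| dt) + clip_accel(urge) dt )`
#'
#' @param velocity current velocity (vx, vy) in m/s.
#' @param urge steering vector from [compute_urges()].
#' @param type the [fish_type()].
#' @param diver_active logical: is the diver-reaction urge active this tick
#'   (permits burst speed)?
#' @param dt time step in seconds (default 0.1).
#' @return the new velocity (length-2 numeric).
#' @export
update_velocity <- function(velocity, urge, type, diver_active = FALSE,
                            dt = 0.1) {
  un <- sqrt(sum(urge^2))
  if (un > type$max_acceleration_m_s2)
    urge <- urge * type$max_acceleration_m_s2 / un
  spd <- sqrt(sum(velocity^2))
  decay <- max(0, 1 - type$drag_constant * spd * dt)
  v2 <- velocity * decay + urge * dt
  cap <- if (diver_active) type$burst_speed_m_s else
    type$max_sustained_speed_m_s
  s2 <- sqrt(sum(v2^2))
  if (s2 > cap) v2 <- v2 * cap / s2
  as.numeric(v2)
}

#' Behavioural state re-pick
#'
#' Draws the next behavioural state for `n` fish by a frequency-weighted
#' random pick with replacement (independent of the current state — a
#' frequent behaviour can be picked repeatedly), then redraws each fish's
#' hidden flag as a Bernoulli trial with probability `1 - detectability` of
#' the new state.  In the simulation this runs for every fish at every
#' 10-model-second boundary.
#'
#' @param type the [fish_type()].
#' @param n number of fish to draw for.
#' @return a data frame with columns `state` (1-based index into
#'   `type$states`) and `hidden` (logical).
#' @export
maybe_switch_state <- function(type, n = 1) {
  cum <- cumsum(type$states$frequency)
  cum[length(cum)] <- 1
  u <- matrix(runif(2 * n), nrow = 2)
  state <- findInterval(u[1, ], cum, left.open = TRUE) + 1L
  hidden <- u[2, ] > type$states$detectability[state]
  data.frame(state = state, hidden = hidden)
}

#' Is a fish visible (behaviourally)?
#'
#' A fish is behaviourally visible when its hidden flag — drawn from its
#' current state's detectability at the last behaviour change — is off.
#' Geometric visibility (range, view cone, sampling-unit limits) is the
#' diver's side of the test; see [visible_fish()].
#'
#' @param fish a list with element `hidden`, or a logical vector of hidden
#'   flags.
#' @return logical.
#' @export
is_visible <- function(fish) {
  if (is.list(fish)) !as.logical(fish$hidden) else !as.logical(fish)
}
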