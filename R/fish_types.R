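#' Construct a fish type
#'
#' A fish type bundles the fixed attributes of a behavioural archetype
#' (size, speeds, perception geometry, reaction distances to the diver)
#' with a repertoire of one to four behavioural states.  Each state carries
#' a pick frequency, a detectability (the probability that a fish in that
#' state is visible to the diver, redrawn as a Bernoulli trial at every
#' behaviour change), a schooling flag and the signed weights of the eight
#' steering urges.
#'
#' @param name character label for the type.
#' @param size_m body length in metres.
#' @param id_distance_m range (m) at which the fish starts reacting to the
#'   diver.
#' @param approach_distance_m standoff distance (m): the diver-reaction urge
#'   ramps from zero at `id_distance_m` to full magnitude here.  For
#'   diver-attracted states (negative `diver_avoidance` weight) the urge
#'   switches off inside this distance, so the fish holds station instead of
#'   climbing onto the diver.
#' @param perception_distance_m schoolmate perception radius (m); only used
#'   by schooling states, may be `NA` otherwise.
#' @param perception_angle_deg total perception cone in degrees, centred on
#'   the current heading (360 means all-round perception).
#' @param max_acceleration_m_s2 cap on the magnitude of the summed steering
#'   vector (m/s^2).
#' @param max_sustained_speed_m_s ordinary speed ceiling (m/s).
#' @param burst_speed_m_s speed ceiling while reacting to the diver (m/s);
#'   must be at least the sustained speed.
#' @param states data frame with one row per behavioural state and columns
#'   `state`, `frequency`, `detectability`, `schooling`,
#'   `schooling_distance_bl`, `patch_distance_m`, `align`, `centre`,
#'   `spacing`, `wander`, `rest`, `cruise`, `patch_gathering`,
#'   `diver_avoidance`.
#' @param drag_constant quadratic friction-drag coefficient (1/m).  The
#'   default `max_acceleration_m_s2 / burst_speed_m_s^2` makes the burst
#'   speed the drag-limited ceiling under full steering effort, while the
#'   sustained-speed clip sets the ordinary cruise plateau.
#'
#' @return an object of class `fc_fish_type`.
#' @seealso [builtin_fish_types()], [read_fish_type()]
#' @export
fish_type <- function(name, size_m, id_distance_m, approach_distance_m,
                      perception_distance_m = NA_real_,
                      perception_angle_deg, max_acceleration_m_s2,
                      max_sustained_speed_m_s, burst_speed_m_s, states,
                      drag_constant = max_acceleration_m_s2 /
                        burst_speed_m_s^2) {
  x <- structure(
    list(
      name = as.character(name),
      size_m = as.numeric(size_m),
      id_distance_m = as.numeric(id_distance_m),
      approach_distance_m = as.numeric(approach_distance_m),
      perception_distance_m = as.numeric(perception_distance_m),
      perception_angle_deg = as.numeric(perception_angle_deg),
      max_acceleration_m_s2 = as.numeric(max_acceleration_m_s2),
      max_sustained_speed_m_s = as.numeric(max_sustained_speed_m_s),
      burst_speed_m_s = as.numeric(burst_speed_m_s),
      drag_constant = as.numeric(drag_constant),
      states = as.data.frame(states)
    ),
    class = "fc_fish_type"
  )
  validate_fish_type(x)
}

state_columns <- c("state", "frequency", "detectability", "schooling",
                   "schooling_distance_bl", "patch_distance_m",
                   "align", "centre", "spacing", "wander", "rest", "cruise",
                   "patch_gathering", "diver_avoidance")

#' Validate a fish type
#'
#' Checks the structural invariants of a fish type: one to four behavioural
#' states, frequencies in \[0, 1\] summing to one (tolerance 1e-9),
#' detectabilities in \[0, 1\], positive speeds with burst at least the
#' sustained speed, positive acceleration, perception angle in (0, 360\],
#' and a perception distance wherever a schooling state needs one.
#'
#' @param x an `fc_fish_type`.
#' @return `x`, invisibly unchanged, or an error describing the first
#'   violated invariant.
#' @export
validate_fish_type <- function(x) {
  st <- x$states
  missing_cols <- setdiff(state_columns, names(st))
  if (length(missing_cols) > 0L)
    stop("fish type '", x$name, "': missing state columns: ",
         paste(missing_cols, collapse = ", "))
  ns <- nrow(st)
  if (ns < 1L || ns > 4L)
    stop("fish type '", x$name, "': must have 1-4 behavioural states, got ",
         ns)
  if (any(st$frequency < 0 | st$frequency > 1))
    stop("fish type '", x$name, "': state frequencies must lie in [0, 1]")
  if (abs(sum(st$frequency) - 1) > 1e-9)
    stop("fish type '", x$name, "': state frequencies sum to ",
         format(sum(st$frequency)), ", not 1")
  if (any(st$detectability < 0 | st$detectability > 1))
    stop("fish type '", x$name, "': detectability must lie in [0, 1]")
  for (f in c("size_m", "id_distance_m", "approach_distance_m",
              "max_acceleration_m_s2", "max_sustained_speed_m_s",
              "burst_speed_m_s")) {
    if (!is.finite(x[[f]]) || x[[f]] <= 0)
      stop("fish type '", x$name, "': ", f, " must be positive")
  }
  if (x$burst_speed_m_s < x$max_sustained_speed_m_s)
    stop("fish type '", x$name,
         "': burst speed must be >= max sustained speed")
  if (!is.finite(x$perception_angle_deg) ||
      x$perception_angle_deg <= 0 || x$perception_angle_deg > 360)
    stop("fish type '", x$name, "': perception angle must be in (0, 360]")
  if (any(as.logical(st$schooling)) &&
      (!is.finite(x$perception_distance_m) || x$perception_distance_m <= 0))
    stop("fish type '", x$name,
         "': schooling states need a positive perception distance")
  bad_patch <- st$patch_gathering != 0 &
    !(is.finite(st$patch_distance_m) & st$patch_distance_m >= 0)
  if (any(bad_patch))
    stop("fish type '", x$name, "': state(s) ",
         paste(st$state[bad_patch], collapse = ", "),
         " use the patch urge but have no patch distance")
  invisible(x)
}

#' @export
print.fc_fish_type <- function(x, ...) {
  cat("<fc_fish_type> ", x$name, "\n", sep = "")
  cat(sprintf("  size %.2f m | id %.1f m | approach %.1f m | cone %g deg\n",
              x$size_m, x$id_distance_m, x$approach_distance_m,
              x$perception_angle_deg))
  cat(sprintf("  accel %.2f m/s^2 | sustained %.2f m/s | burst %.2f m/s\n",
              x$max_acceleration_m_s2, x$max_sustained_speed_m_s,
              x$burst_speed_m_s))
  cat("  states:", paste(sprintf("%s (%.2f)", x$states$state,
                                 x$states$frequency), collapse = ", "), "\n")
  invisible(x)
}

fixed_fields <- c(
  name = "name", size_m = "size_m", id_distance_m = "id_distance_m",
  approach_distance_m = "approach_distance_m",
  perception_distance_m = "perception_distance_m",
  perception_angle_deg = "perception_angle_deg",
  max_acceleration_m_s2 = "max_acceleration_m_s2",
  max_sustained_speed_m_s = "max_sustained_speed_m_s",
  burst_speed_m_s = "burst_speed_m_s"
)

#' Read a fish type from CSV
#'
#' The file holds two comma-separated blocks split by a blank line: a
#' fixed-attribute block (`attribute,value` rows) and a state block whose
#' header names the behavioural states, with one row per state attribute.
#' Missing entries (for example the patch distance of a state without a
#' patch urge) are left empty.  [write_fish_type()] writes the same layout,
#' and a load-save-load round trip is identical.
#'
#' @param path path to a fish-type CSV file.
#' @return a validated `fc_fish_type`.
#' @export
read_fish_type <- function(path) {
  lines <- readLines(path)
  blank <- which(!nzchar(trimws(lines)))
  if (length(blank) == 0L)
    stop("fish type file '", path,
         "': expected two blocks separated by a blank line")
  b1 <- lines[seq_len(blank[1] - 1L)]
  b2 <- lines[seq(blank[1] + 1L, length(lines))]
  b2 <- b2[nzchar(trimws(b2))]
  fixed <- read.csv(text = paste(b1, collapse = "\n"),
                    stringsAsFactors = FALSE)
  if (!all(c("attribute", "value") %in% names(fixed)))
    stop("fish type file '", path,
         "': first block needs 'attribute,value' columns")
  fx <- setNames(fixed$value, fixed$attribute)
  need <- setdiff(names(fixed_fields), names(fx))
  if (length(need) > 0L)
    stop("fish type file '", path, "': missing attribute(s): ",
         paste(need, collapse = ", "))
  sb <- read.csv(text = paste(b2, collapse = "\n"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  if (names(sb)[1] != "attribute")
    stop("fish type file '", path,
         "': second block must start with an 'attribute' column")
  state_names <- names(sb)[-1]
  rows <- setNames(
    lapply(seq_len(nrow(sb)), function(i) unlist(sb[i, -1])), sb$attribute)
  need <- setdiff(setdiff(state_columns, "state"), names(rows))
  if (length(need) > 0L)
    stop("fish type file '", path, "': missing state attribute(s): ",
         paste(need, collapse = ", "))
  num <- function(field) suppressWarnings(as.numeric(rows[[field]]))
  states <- data.frame(
    state = state_names,
    frequency = num("frequency"),
    detectability = num("detectability"),
    schooling = as.logical(rows[["schooling"]]),
    schooling_distance_bl = num("schooling_distance_bl"),
    patch_distance_m = num("patch_distance_m"),
    align = num("align"), centre = num("centre"), spacing = num("spacing"),
    wander = num("wander"), rest = num("rest"), cruise = num("cruise"),
    patch_gathering = num("patch_gathering"),
    diver_avoidance = num("diver_avoidance"),
    stringsAsFactors = FALSE
  )
  # empty weight cells mean "urge unused": zero weight
  for (w in c("align", "centre", "spacing", "wander", "rest", "cruise",
              "patch_gathering", "diver_avoidance"))
    states[[w]][is.na(states[[w]])] <- 0
  states$schooling[is.na(states$schooling)] <- FALSE
  fish_type(
    name = fx[["name"]],
    size_m = as.numeric(fx[["size_m"]]),
    id_distance_m = as.numeric(fx[["id_distance_m"]]),
    approach_distance_m = as.numeric(fx[["approach_distance_m"]]),
    perception_distance_m = suppressWarnings(
      as.numeric(fx[["perception_distance_m"]])),
    perception_angle_deg = as.numeric(fx[["perception_angle_deg"]]),
    max_acceleration_m_s2 = as.numeric(fx[["max_acceleration_m_s2"]]),
    max_sustained_speed_m_s = as.numeric(fx[["max_sustained_speed_m_s"]]),
    burst_speed_m_s = as.numeric(fx[["burst_speed_m_s"]]),
    states = states
  )
}

#' Write a fish type to CSV
#'
#' @param x an `fc_fish_type`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fish_type <- function(x, path) {
  fmt <- function(v) {
    ifelse(is.na(v), "", vapply(v, function(z) format(z, digits = 15), ""))
  }
  fixed_vals <- c(
    x$name, fmt(x$size_m), fmt(x$id_distance_m), fmt(x$approach_distance_m),
    fmt(x$perception_distance_m), fmt(x$perception_angle_deg),
    fmt(x$max_acceleration_m_s2), fmt(x$max_sustained_speed_m_s),
    fmt(x$burst_speed_m_s))
  b1 <- c("attribute,value",
          paste(names(fixed_fields), fixed_vals, sep = ","))
  st <- x$states
  row_line <- function(field) {
    vals <- st[[field]]
    if (field == "schooling") vals <- as.character(as.logical(vals))
    else if (is.numeric(vals)) vals <- fmt(vals)
    paste(c(field, vals), collapse = ",")
  }
  b2 <- c(paste(c("attribute", st$state), collapse = ","),
          vapply(setdiff(state_columns, "state"), row_line, ""))
  writeLines(c(b1, "", b2), path)
  invisible(path)
}

#' The four packaged behavioural trait archetypes
#'
#' Returns the packaged parameterisations of the four trait archetypes used
#' in the survey-design experiment: `schooling` (small shoaling sparid-like
#' fish), `cryptic` (small site-attached blenniid-like fish with low,
#' state-dependent detectability), `shy` (labrid-like fish that keep a ~3 m
#' standoff from the diver) and `bold` (the same fish but attracted to the
#' diver while wandering).
#'
#' @param name optional single type name; when given, that type alone is
#'   returned.
#' @return a named list of `fc_fish_type` objects, or a single object when
#'   `name` is given.
#' @export
builtin_fish_types <- function(name = NULL) {
  dir <- system.file("extdata", "fish_types", package = "fishcensus")
  all <- c("schooling", "cryptic", "shy", "bold")
  if (!is.null(name)) {
    name <- match.arg(name, all)
    return(read_fish_type(file.path(dir, paste0(name, ".csv"))))
  }
  setNames(
    lapply(all, function(n) read_fish_type(file.path(dir, paste0(n, ".csv")))),
    all)
}

# engine-facing flat representation of a fish type
ft_engine <- function(type) {
  st <- type$states
  pd <- st$patch_distance_m
  pd[!is.finite(pd)] <- 0
  percep <- type$perception_distance_m
  if (!is.finite(percep)) percep <- 0
  list(
    size = type$size_m,
    id_dist = type$id_distance_m,
    approach_dist = type$approach_distance_m,
    percep_dist = percep,
    percep_angle = type$perception_angle_deg,
    max_accel = type$max_acceleration_m_s2,
    max_sustained_speed = type$max_sustained_speed_m_s,
    burst_speed = type$burst_speed_m_s,
    drag_k = type$drag_constant,
    freq = as.numeric(st$frequency),
    detect = as.numeric(st$detectability),
    school = as.integer(as.logical(st$schooling)),
    school_dist_m = ifelse(is.finite(st$schooling_distance_bl),
                           st$schooling_distance_bl * type$size_m, 0),
    patch_dist = as.numeric(pd),
    w_align = as.numeric(st$align), w_centre = as.numeric(st$centre),
    w_spacing = as.numeric(st$spacing), w_wander = as.numeric(st$wander),
    w_rest = as.numeric(st$rest), w_cruise = as.numeric(st$cruise),
    w_patch = as.numeric(st$patch_gathering),
    w_diver = as.numeric(st$diver_avoidance)
  )
}
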