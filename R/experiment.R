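#' Survey-design parameter grid
#'
#' The factorial designs of the survey-design experiment.  Transects cross
#' five lengths (10-50 m), five widths (1-5 m) and five swim speeds
#' (2-10 m/min): 125 combinations.  Point counts cross four radii (2-5 m),
#' five durations (3-11 min) and five rotation speeds (2-10 deg/s): 100
#' combinations.  Radii of 1 m (dominated by diver presence) and 6 m
#' (matching the visibility limit) are excluded.
#'
#' @param protocol `"transect"` or `"point"`.
#' @return a data frame, one row per parameter combination.
#' @export
parameter_grid <- function(protocol = c("transect", "point")) {
  protocol <- match.arg(protocol)
  if (protocol == "transect")
    expand.grid(length_m = c(10, 20, 30, 40, 50),
                width_m = 1:5,
                speed_m_min = c(2, 4, 6, 8, 10))
  else
    expand.grid(radius_m = 2:5,
                time_min = c(3, 5, 7, 9, 11),
                rotation_deg_s = c(2, 4, 6, 8, 10))
}

#' Run a bias/precision sweep
#'
#' Runs `replicates` independent survey replicates for every parameter
#' combination in `grid`, at a fixed true density, and summarises each
#' combination ("cell") into bias and precision statistics:
#'
#' * `bias_pct = 100 * |mean(De) - Dt| / Dt` — absolute relative deviation
#'   of the mean estimated density from the true density;
#' * `bias_signed_pct = 100 * (mean(De) - Dt) / Dt` — the signed version
#'   (positive values are overestimates);
#' * `cv_pct = 100 * sd(De) / Dt` — the coefficient of variation of the
#'   replicate estimates as a percentage of true density.
#'
#' Replicate `r` of every cell uses seed `base_seed + r`, so a sweep is
#' fully reproducible from `base_seed`, and fish locations are reshuffled
#' for every replicate.  The reference design uses 10 replicates per cell;
#' smaller replicate counts are supported for desk-scale runs and flagged
#' in the output (`scale` attribute and `reduced` column).
#'
#' @param protocol `"transect"` or `"point"`.
#' @param type an [fish_type()] (or the name of a packaged type).
#' @param grid parameter grid (default the full [parameter_grid()]).
#' @param replicates replicate surveys per cell (at least 2, for the CV).
#' @param base_seed integer; replicate r uses seed `base_seed + r`.
#' @param world an [world_config()].
#' @param view_angle_deg diver field of view, degrees.
#' @param progress print a line per cell as the sweep runs.
#' @return an object of class `fc_sweep`: list with `runs` (one row per
#'   replicate survey) and `cells` (one row per parameter combination).
#' @export
run_sweep <- function(protocol = c("transect", "point"), type,
                      grid = NULL, replicates = 10, base_seed = 1,
                      world = world_config(), view_angle_deg = 160,
                      progress = FALSE) {
  protocol <- match.arg(protocol)
  if (is.character(type)) type <- builtin_fish_types(type)
  stopifnot(inherits(type, "fc_fish_type"))
  if (is.null(grid)) grid <- parameter_grid(protocol)
  if (replicates < 2)
    stop("need at least 2 replicates per cell to compute a CV")
  full <- parameter_grid(protocol)
  reduced <- replicates < 10 || nrow(grid) < nrow(full)
  pnames <- names(grid)
  runs <- vector("list", nrow(grid) * replicates)
  k <- 0L
  for (i in seq_len(nrow(grid))) {
    sv <- do.call(survey_config,
                  c(list(protocol = protocol,
                         view_angle_deg = view_angle_deg),
                    as.list(grid[i, , drop = FALSE])))
    for (r in seq_len(replicates)) {
      res <- run_survey(world, type, sv, seed = base_seed + r)
      k <- k + 1L
      runs[[k]] <- cbind(data.frame(cell = i), as.data.frame(res),
                         data.frame(replicate = r))
    }
    if (progress)
      message(sprintf("[%s/%s] %s %s: %s", i, nrow(grid), type$name,
                      protocol,
                      paste(pnames, grid[i, ], sep = "=", collapse = " ")))
  }
  runs <- do.call(rbind, runs)
  runs$bias_signed <- (runs$density - runs$true_density) /
    runs$true_density
  dt <- world$true_density
  cells <- grid
  agg <- t(vapply(seq_len(nrow(grid)), function(i) {
    de <- runs$density[runs$cell == i]
    c(mean_density = mean(de),
      bias_pct = 100 * abs(mean(de) - dt) / dt,
      bias_signed_pct = 100 * (mean(de) - dt) / dt,
      cv_pct = 100 * sd(de) / dt)
  }, numeric(4)))
  cells <- cbind(cells, as.data.frame(agg))
  cells$trait <- type$name
  cells$protocol <- protocol
  cells$replicates <- replicates
  cells$reduced <- reduced
  structure(
    list(runs = runs, cells = cells, protocol = protocol,
         trait = type$name, replicates = replicates,
         base_seed = base_seed, true_density = dt,
         scale = if (reduced) "reduced" else "full"),
    class = "fc_sweep")
}

#' @export
print.fc_sweep <- function(x, ...) {
  cat(sprintf(
    "<fc_sweep> %s | %s | %d cells x %d replicates (%s scale) | Dt %g\n",
    x$trait, x$protocol, nrow(x$cells), x$replicates, x$scale,
    x$true_density))
  cat(sprintf("  mean bias %.1f%% (%.1f-%.1f) | mean CV %.1f%%\n",
              mean(x$cells$bias_pct), min(x$cells$bias_pct),
              max(x$cells$bias_pct), mean(x$cells$cv_pct)))
  invisible(x)
}

sweep_cells <- function(x) {
  if (inherits(x, "fc_sweep")) return(x$cells)
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, TRUE, "fc_sweep")))
    return(do.call(rbind, lapply(x, `[[`, "cells")))
  as.data.frame(x)
}

#' Trait-level bias and precision summary
#'
#' Aggregates sweep cells into the trait-level table: the unweighted mean
#' and the min-max range of cell bias and CV across all parameter
#' combinations, per trait and protocol.
#'
#' @param x an `fc_sweep`, a list of them, or a cells data frame.
#' @return a data frame with one row per (trait, protocol) and columns
#'   `mean_bias_pct`, `min_bias_pct`, `max_bias_pct`, `mean_cv_pct`,
#'   `min_cv_pct`, `max_cv_pct`, `n_cells`.
#' @export
summarise_trait <- function(x) {
  cells <- sweep_cells(x)
  if (nrow(cells) < 1) stop("no cells to summarise")
  key <- interaction(cells$trait, cells$protocol, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    cc <- cells[key == k, ]
    data.frame(trait = cc$trait[1], protocol = cc$protocol[1],
               mean_bias_pct = mean(cc$bias_pct),
               min_bias_pct = min(cc$bias_pct),
               max_bias_pct = max(cc$bias_pct),
               mean_cv_pct = mean(cc$cv_pct),
               min_cv_pct = min(cc$cv_pct),
               max_cv_pct = max(cc$cv_pct),
               n_cells = nrow(cc), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

grid_param_names <- function(protocol) {
  if (protocol == "transect") c("length_m", "width_m", "speed_m_min")
  else c("radius_m", "time_min", "rotation_deg_s")
}

#' Per-trait shading of sweep cells
#'
#' Rescales each metric to \[0, 1\] within each trait (and protocol), the
#' scaling used by the heatmap panels: the darkest shade is the worst cell
#' of that trait, so panels are comparable within a trait but not across
#' traits.
#'
#' @param x an `fc_sweep`, list of sweeps, or cells data frame.
#' @param metrics which cell metrics to shade.
#' @return a long data frame with columns of the grid parameters plus
#'   `trait`, `protocol`, `metric`, `value` and `shade`.
#' @export
heatmap_data <- function(x, metrics = c("bias_pct", "cv_pct")) {
  cells <- sweep_cells(x)
  out <- lapply(metrics, function(m) {
    d <- cells
    d$metric <- m
    d$value <- d[[m]]
    key <- interaction(d$trait, d$protocol, drop = TRUE)
    d$shade <- stats::ave(d$value, key, FUN = function(v) {
      rng <- range(v)
      if (diff(rng) < 1e-12) rep(0, length(v))
      else (v - rng[1]) / diff(rng)
    })
    d
  })
  do.call(rbind, out)
}

#' Export bias/precision heatmaps and matrix CSVs
#'
#' Writes, per (trait, metric), a faceted heatmap figure (PNG) in the
#' style of the experiment's summary panels — the two fastest-varying grid
#' parameters on the axes, facets over the third, darker tiles meaning
#' more bias or more variability, shading scaled to the range of each
#' trait — plus a wide CSV matrix of the same numbers for figure-free
#' comparison.
#'
#' @param x an `fc_sweep`, a list of sweeps (one per trait), or a cells
#'   data frame; the grid must be complete (every combination of the
#'   parameter levels present).
#' @param dir output directory, created if needed.
#' @param metrics cell metrics to export.
#' @return invisibly, the paths written.
#' @export
heatmap_export <- function(x, dir, metrics = c("bias_pct", "cv_pct")) {
  cells <- sweep_cells(x)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  shaded <- heatmap_data(x, metrics)
  paths <- character(0)
  for (proto in unique(cells$protocol)) {
    pn <- grid_param_names(proto)
    for (trait in unique(cells$trait[cells$protocol == proto])) {
      cc <- cells[cells$protocol == proto & cells$trait == trait, ]
      lv <- lapply(pn, function(p) sort(unique(cc[[p]])))
      want <- expand.grid(lv[[1]], lv[[2]], lv[[3]])
      names(want) <- pn
      have <- do.call(paste, cc[pn])
      missing <- want[!(do.call(paste, want) %in% have), , drop = FALSE]
      if (nrow(missing) > 0)
        stop("incomplete grid for ", trait, " ", proto, "; missing cells: ",
             paste(apply(missing, 1, paste, collapse = "/"),
                   collapse = ", "))
      for (m in metrics) {
        # wide matrix: rows = param1 x param2, columns = param3 levels
        wide <- reshape(
          cc[c(pn, m)], direction = "wide",
          idvar = pn[1:2], timevar = pn[3])
        csv <- file.path(dir, sprintf("%s_%s_%s.csv", trait, proto, m))
        write.csv(wide, csv, row.names = FALSE)
        sh <- shaded[shaded$protocol == proto & shaded$trait == trait &
                       shaded$metric == m, ]
        p <- ggplot2::ggplot(sh, ggplot2::aes(
          x = factor(.data[[pn[1]]]), y = factor(.data[[pn[2]]]),
          fill = shade)) +
          ggplot2::geom_tile() +
          ggplot2::facet_wrap(
            stats::as.formula(paste("~", pn[3])),
            labeller = ggplot2::label_both, nrow = 1) +
          ggplot2::scale_fill_gradient(
            low = "grey95", high = "grey10", limits = c(0, 1),
            name = m) +
          ggplot2::labs(x = pn[1], y = pn[2],
                        title = sprintf("%s / %s / %s", trait, proto, m)) +
          ggplot2::theme_minimal()
        fig <- file.path(dir, sprintf("%s_%s_%s.png", trait, proto, m))
        ggplot2::ggsave(fig, p, width = 10, height = 2.8, dpi = 150)
        paths <- c(paths, csv, fig)
      }
    }
  }
  invisible(paths)
}

#' Descriptive regression summary of a sweep
#'
#' Convenience wrapper fitting, per trait and protocol, a multiple linear
#' regression of (transformed) cell bias on the three survey parameters
#' with all main effects and two-way interactions.  Purely descriptive: a
#' quick check of effect directions and fit, not an inferential analysis.
#'
#' @param x an `fc_sweep`, list of sweeps, or cells data frame.
#' @param transform transformation applied to `bias_pct` before fitting
#'   (default `log1p`, which tames the heavy right tail).
#' @return a list, one entry per (trait, protocol), each with the fitted
#'   `lm`, its coefficient table and the multiple R-squared.
#' @export
regression_summary <- function(x, transform = log1p) {
  cells <- sweep_cells(x)
  key <- interaction(cells$trait, cells$protocol, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    cc <- cells[key == k, ]
    pn <- grid_param_names(cc$protocol[1])
    cc$.resp <- transform(cc$bias_pct)
    fml <- as.formula(paste(".resp ~ (", paste(pn, collapse = " + "),
                            ")^2"))
    fit <- lm(fml, data = cc)
    s <- summary(fit)
    list(trait = cc$trait[1], protocol = cc$protocol[1], fit = fit,
         coefficients = s$coefficients, r_squared = s$r.squared)
  })
  setNames(out, levels(key))
}

#' Marginal mean bias along one survey parameter
#'
#' Averages cell bias over the other grid parameters, giving the marginal
#' response of bias to one design choice (for example survey time in point
#' counts).  Used by the directional checks on the sweep results.
#'
#' @param x an `fc_sweep` or cells data frame.
#' @param param grid parameter name.
#' @param metric cell metric to average (default `bias_pct`).
#' @return a data frame with the parameter levels and the marginal means.
#' @export
marginal_bias <- function(x, param, metric = "bias_pct") {
  cells <- sweep_cells(x)
  lev <- sort(unique(cells[[param]]))
  data.frame(
    level = lev,
    mean = vapply(lev, function(l) mean(cells[[metric]][cells[[param]] == l]),
                  numeric(1)))
}
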