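# Micromanipulation-style force spectroscopy: axial stretching by moving
# harmonic anchors coupled to pole groups of lamina subunits, optional
# uniaxial plate compression, spring-constant estimation and replicate
# statistics.
#
# Full-scale protocol: K = 20 kT/sigma^2, v_pull = 0.1 sigma/tau (tau = 500
# steps), 80 lamina subunits per pole at |y| >= 28 sigma, anchors nominally
# launched from y0 = +/- 60 sigma, 2e5 steps reaching strains of ~80%.
# Reduced-scale protocols keep K and v_pull in intrinsic units and scale
# pole_cut, y0 and the pole group size with shell radius and lamina count,
# preserving the dimensionless loading (anchor travel per pole = 40/29 R0).

#' Build a pulling protocol
#'
#' With only a nucleus supplied, all geometric parameters scale from the
#' full-scale protocol by the ratio of the nucleus' relaxed radius to the
#' full-scale 29 sigma (and the pole group by the lamina count), keeping
#' `K` and `v_pull` in intrinsic units.
#'
#' @param nucleus A relaxed `nm_nucleus` used for scaling defaults.
#' @param K Anchor spring stiffness (kT/sigma^2, default 20).
#' @param v_pull Anchor speed (sigma/tau, default 0.1).
#' @param n_pole Lamina subunits pulled per pole.
#' @param pole_cut |y| threshold for pole membership (sigma).
#' @param y0 Nominal anchor track origin (sigma, metadata only; anchors start
#'   at the pole-group centers so that initial spring extension is zero).
#' @param n_steps Total integration steps.
#' @param record_every Snapshot cadence (steps).
#' @param series_every Force/extension series cadence (steps).
#' @param axis Pulling axis (default `"y"`).
#' @return An `nm_protocol` list.
#' @export
pull_protocol <- function(nucleus = NULL, K = 20, v_pull = 0.1,
                          n_pole = NULL, pole_cut = NULL, y0 = NULL,
                          n_steps = NULL, record_every = TAU_STEPS,
                          series_every = TAU_STEPS, axis = "y") {
  if (!is.null(nucleus)) {
    r0 <- if (is.finite(nucleus$R0)) nucleus$R0 else shell_radius(nucleus)
    if (is.null(n_pole)) n_pole <- max(4L, round(80 * nucleus$n_lamina / 15000))
    if (is.null(pole_cut)) {
      # nominal full-scale proportion 28/29 R0, backed off where the shell's
      # shape fluctuations would leave a cap with too few candidates
      ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
      lam <- nucleus$positions[lamina_indices(nucleus), ax]
      lam <- lam - mean(lam)
      want <- 3L * n_pole
      cap_n <- sort(lam, decreasing = TRUE)[min(want, length(lam))]
      cap_s <- sort(-lam, decreasing = TRUE)[min(want, length(lam))]
      pole_cut <- min(28 / 29 * r0, cap_n, cap_s) - 1e-9
    }
    if (is.null(y0)) y0 <- 60 / 29 * r0
    if (is.null(n_steps)) {
      n_steps <- as.integer(round(40 / 29 * r0 / v_pull) * TAU_STEPS)
    }
  }
  if (is.null(n_pole) || is.null(pole_cut) || is.null(n_steps)) {
    abort("supply `nucleus` or all of `n_pole`, `pole_cut`, `n_steps`")
  }
  if (K <= 0 || v_pull < 0 || n_pole < 1) {
    abort("need K > 0, v_pull >= 0, n_pole >= 1")
  }
  if (!is.null(y0) && pole_cut >= y0) abort("`pole_cut` must be below `y0`")
  structure(list(K = K, v_pull = v_pull, n_pole = as.integer(n_pole),
                 pole_cut = pole_cut, y0 = y0, n_steps = as.integer(n_steps),
                 record_every = as.integer(record_every),
                 series_every = as.integer(series_every),
                 axis = match.arg(axis, c("x", "y", "z"))),
            class = "nm_protocol")
}

axis_index <- function(axis) match(axis, c("x", "y", "z"))

#' Select the pulled pole subunits
#'
#' Uniform samples (without replacement) of `n_pole` lamina subunits from
#' each pole cap (axial coordinate at least `pole_cut` in magnitude).
#'
#' @param nucleus An `nm_nucleus`.
#' @param protocol An `nm_protocol`.
#' @param seed Integer seed.
#' @return List with integer index vectors `north` and `south` (disjoint).
#' @export
select_pulled_subunits <- function(nucleus, protocol, seed = 1L) {
  ax <- axis_index(protocol$axis)
  lam <- lamina_indices(nucleus)
  coord <- nucleus$positions[lam, ax]
  coord <- coord - mean(coord)  # cap membership about the nucleus center
  north <- lam[coord >= protocol$pole_cut]
  south <- lam[coord <= -protocol$pole_cut]
  if (length(north) < protocol$n_pole || length(south) < protocol$n_pole) {
    abort(sprintf(
      "pole caps at |%s| >= %.2f hold %d/%d candidates but n_pole = %d; lower `pole_cut`",
      protocol$axis, protocol$pole_cut, length(north), length(south),
      protocol$n_pole))
  }
  local_seed(seed, list(north = sort(sample(north, protocol$n_pole)),
                        south = sort(sample(south, protocol$n_pole))))
}

#' Stretch a nucleus with moving harmonic anchors
#'
#' Each pole group's center of mass is restrained along the pulling axis by
#' a harmonic spring of stiffness `K` to an anchor moving outward at
#' `v_pull`; anchors start at the group centers (zero initial spring
#' extension). Per-frame restraint forces, extension
#' \eqn{\Delta L} (change in distance between pole-group centers) and strain
#' \eqn{\lambda = \Delta L / R_0} are recorded.
#'
#' @param state An `nm_state` whose nucleus already carries any tether or
#'   crosslink bonds.
#' @param protocol An `nm_protocol` from [pull_protocol()].
#' @param seed Integer seed (pole selection; thermostat noise comes from the
#'   state seed).
#' @return An `nm_pull` object: `curve` (an `nm_curve` tibble: `step`,
#'   `time_tau`, `anchor_y`, `force`, `extension`, `strain`), `frames`,
#'   `frame_steps`, `frame_strain`, final `state`, `pulled` index sets.
#' @export
stretch <- function(state, protocol, seed = 1L) {
  stopifnot(inherits(state, "nm_state"), inherits(protocol, "nm_protocol"))
  state$nucleus <- recenter_nucleus(state$nucleus)
  nuc <- state$nucleus
  pulled <- select_pulled_subunits(nuc, protocol, seed)
  engine_protocol <- list(
    type = "stretch", idx_north = pulled$north, idx_south = pulled$south,
    stiffness = protocol$K, step_speed = protocol$v_pull / TAU_STEPS,
    axis = axis_index(protocol$axis))
  traj <- run_dynamics(state, protocol$n_steps,
                       record_every = protocol$record_every,
                       series_every = protocol$series_every,
                       protocol = engine_protocol)
  r0 <- if (is.finite(nuc$R0)) nuc$R0 else shell_radius(nuc)
  s <- traj$series
  sep0 <- s$com_north[1] - s$com_south[1]
  curve <- tibble::tibble(
    step = s$step,
    time_tau = s$step / TAU_STEPS,
    anchor_y = s$anchor_north,
    force = (s$force_north - s$force_south) / 2,
    extension = (s$com_north - s$com_south) - sep0,
    strain = ((s$com_north - s$com_south) - sep0) / r0)
  curve <- structure(curve, R0 = r0, K = protocol$K, v_pull = protocol$v_pull,
                     class = c("nm_curve", class(curve)))
  frame_strain <- stats::approx(curve$step, curve$strain,
                                xout = traj$frame_steps, rule = 2)$y
  structure(list(curve = curve, frames = traj$frames,
                 frame_steps = traj$frame_steps, frame_strain = frame_strain,
                 state = traj$state, pulled = pulled, protocol = protocol),
            class = "nm_pull")
}

#' Local nuclear spring constant from a force-strain curve
#'
#' Least-squares slope of restraint force versus extension within a strain
#' window centered on `strain_target` (the effective nuclear spring constant
#' k_nuc, in kT/sigma^2, i.e. per unit extension in sigma).
#'
#' @param curve An `nm_curve` (or any tibble with `force`, `extension`,
#'   `strain` columns).
#' @param strain_target Center of the strain window (default 0.30).
#' @param window Half-width of the window in strain (default 0.05).
#' @return k_nuc (scalar).
#' @export
spring_constant <- function(curve, strain_target = 0.30, window = 0.05) {
  lo <- strain_target - window
  hi <- strain_target + window
  if (min(curve$strain) > lo || max(curve$strain) < hi) {
    abort(sprintf(
      "curve spans strain [%.3f, %.3f] but the window needs [%.3f, %.3f]",
      min(curve$strain), max(curve$strain), lo, hi))
  }
  pts <- curve[curve$strain >= lo & curve$strain <= hi, , drop = FALSE]
  if (nrow(pts) < 3) abort("fewer than 3 curve points in the strain window")
  unname(coef(lm(force ~ extension, data = pts))[2])
}

#' Uniaxial plate-compression protocol
#'
#' @param K_wall Wall stiffness (kT/sigma^2, default 20).
#' @param v_plate Plate approach speed per plate (sigma/tau, default 0.1).
#' @param gap_pad Initial clearance between each plate and the nucleus
#'   extent (sigma, default 1).
#' @param n_steps Total integration steps.
#' @param series_every Series cadence (steps).
#' @param record_every Snapshot cadence (steps).
#' @param axis Compression axis (default `"y"`).
#' @return An `nm_plate_protocol` list.
#' @export
plate_protocol <- function(K_wall = 20, v_plate = 0.1, gap_pad = 1,
                           n_steps = 10000L, series_every = TAU_STEPS,
                           record_every = 0L, axis = "y") {
  structure(list(K_wall = K_wall, v_plate = v_plate, gap_pad = gap_pad,
                 n_steps = as.integer(n_steps),
                 series_every = as.integer(series_every),
                 record_every = as.integer(record_every),
                 axis = match.arg(axis, c("x", "y", "z"))),
            class = "nm_plate_protocol")
}

#' Compress a nucleus between two planar walls
#'
#' Two repulsive walls perpendicular to the chosen axis approach at constant
#' speed; the total wall normal force and the plate-gap strain
#' `(gap0 - gap) / gap0` are recorded. The perpendicular directions are
#' unconstrained.
#'
#' @param state An `nm_state`.
#' @param protocol An `nm_plate_protocol`.
#' @return An `nm_compression` object with a `curve` tibble (`step`,
#'   `time_tau`, `gap`, `force`, `strain`), `frames` and the final `state`.
#' @export
compress <- function(state, protocol) {
  stopifnot(inherits(state, "nm_state"), inherits(protocol, "nm_plate_protocol"))
  state$nucleus <- recenter_nucleus(state$nucleus)
  engine_protocol <- list(
    type = "compress", stiffness = protocol$K_wall,
    step_speed = protocol$v_plate / TAU_STEPS,
    axis = axis_index(protocol$axis), gap_pad = protocol$gap_pad)
  traj <- run_dynamics(state, protocol$n_steps,
                       record_every = protocol$record_every,
                       series_every = protocol$series_every,
                       protocol = engine_protocol)
  s <- traj$series
  gap0 <- s$gap[1]
  curve <- tibble::tibble(step = s$step, time_tau = s$step / TAU_STEPS,
                          gap = s$gap, force = s$wall_force,
                          strain = (gap0 - s$gap) / gap0)
  structure(list(curve = curve, frames = traj$frames,
                 frame_steps = traj$frame_steps, state = traj$state,
                 protocol = protocol),
            class = "nm_compression")
}

#' Compressive stiffness from a plate-compression curve
#'
#' Least-squares slope of wall force versus plate displacement within a
#' plate-gap strain window.
#'
#' @param curve Compression curve tibble (`gap`, `force`, `strain`).
#' @param strain_target,window Strain window (as in [spring_constant()]).
#' @return Stiffness (kT/sigma^2).
#' @export
compressive_stiffness <- function(curve, strain_target = 0.2, window = 0.1) {
  pts <- curve[abs(curve$strain - strain_target) <= window, , drop = FALSE]
  if (nrow(pts) < 3) abort("fewer than 3 curve points in the strain window")
  gap0 <- curve$gap[1]
  pts$displacement <- gap0 - pts$gap
  unname(coef(lm(force ~ displacement, data = pts))[2])
}

#' Compare spring constants across simulation conditions
#'
#' One-way ANOVA with post-hoc Tukey HSD pairwise comparisons (or an
#' unpaired, two-sided Student's t-test when exactly two groups are given),
#' plus per-group mean and standard error of the mean.
#'
#' @param groups Named list of numeric replicate vectors, or a data frame
#'   with columns `group` and `value`.
#' @return An `nm_comparison`: `method`, `statistic`, `p_value`, `pairwise`
#'   tibble (`comparison`, `estimate`, `p_adj`), `group_stats` tibble
#'   (`group`, `n`, `mean`, `sem`).
#' @export
compare_conditions <- function(groups) {
  if (is.data.frame(groups)) {
    df <- tibble::tibble(group = as.character(groups$group),
                         value = groups$value)
  } else {
    df <- dplyr::bind_rows(lapply(names(groups), function(g) {
      tibble::tibble(group = g, value = groups[[g]])
    }))
  }
  counts <- table(df$group)
  if (length(counts) < 2 || any(counts < 2)) {
    abort("need >= 2 groups with >= 2 replicates each")
  }
  gs <- df %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$value),
                     sem = sd(.data$value) / sqrt(dplyr::n()),
                     .groups = "drop")
  df$group <- factor(df$group)
  if (length(counts) == 2) {
    tt <- t.test(value ~ group, data = df, var.equal = FALSE)
    lv <- levels(df$group)
    pairwise <- tibble::tibble(
      comparison = paste(lv[2], lv[1], sep = "-"),
      estimate = unname(tt$estimate[2] - tt$estimate[1]),
      p_adj = tt$p.value)
    out <- list(method = "t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, pairwise = pairwise, group_stats = gs)
  } else {
    fit <- aov(value ~ group, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    pairwise <- tibble::tibble(comparison = rownames(tk),
                               estimate = tk[, "diff"],
                               p_adj = tk[, "p adj"])
    out <- list(method = "anova-tukey", statistic = an[["F value"]][1],
                p_value = an[["Pr(>F)"]][1], pairwise = pairwise,
                group_stats = gs)
  }
  structure(out, class = "nm_comparison")
}

#' @describeIn tidy_nucmech Pairwise comparisons of a condition test.
#' @export
tidy.nm_comparison <- function(x, ...) x$pairwise

#' @describeIn tidy_nucmech One-row overall test summary.
#' @export
glance.nm_comparison <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic,
                 p_value = x$p_value, n_groups = nrow(x$group_stats))
}

#' @describeIn tidy_nucmech One-row summary of a pulling run (k_nuc at the
#'   largest strain window available around 0.3, terminal strain, peak force).
#' @export
glance.nm_pull <- function(x, ...) {
  k30 <- tryCatch(spring_constant(x$curve, 0.30, 0.05), error = function(e) NA_real_)
  tibble::tibble(
    k_nuc_30 = k30,
    terminal_strain = x$curve$strain[nrow(x$curve)],
    peak_force = max(x$curve$force),
    n_steps = x$protocol$n_steps)
}

#' @export
print.nm_comparison <- function(x, ...) {
  cat(sprintf("<nm_comparison> %s: statistic = %.3f, p = %.3g\n",
              x$method, x$statistic, x$p_value))
  print(x$group_stats)
  invisible(x)
}

#' @export
print.nm_pull <- function(x, ...) {
  cat(sprintf("<nm_pull> %d curve points, %d frames, terminal strain %.3f\n",
              nrow(x$curve), length(x$frames),
              x$curve$strain[nrow(x$curve)]))
  invisible(x)
}
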