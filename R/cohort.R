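#' Group-level generating presets
#'
#' Default per-group study conditions and GLAMPI parameter distributions
#' used by [cohort_spec()]. Arena sides and trial counts follow the study
#' design (young controls: 3.5 m arena, 12 trials per condition; elderly:
#' 4.5 m, 9 trials; MCI groups: 4.0 m, 9 trials). Parameter means encode
#' the qualitative group differences the analysis is built to detect:
#' healthy elderly with a modest angular over-encoding (`g2 > 1`), angular
#' regression to the mean (`g3 < 1`), near-zero leak and veridical distance
#' production; MCI groups with larger `g2` and angular noise `nu`, most
#' pronounced in the biomarker-positive group.
#'
#' @return Tibble with one row per group label.
#' @export
glampi_presets <- function() {
  tibble::tribble(
    ~group, ~arena_side, ~trials_per_condition, ~speed_mean, ~speed_sd,
    ~k, ~g2, ~beta, ~g3, ~m3, ~sigma, ~nu,
    "young",       3.5, 12L, 0.45, 0.07, 0.95, 1.05, 0.02, 0.85, 0.95, 0.30, 0.35,
    "elderly",     4.5,  9L, 0.55, 0.08, 0.90, 1.10, 0.05, 0.80, 1.00, 0.35, 0.45,
    "mci_unknown", 4.0,  9L, 0.55, 0.08, 0.85, 1.25, 0.08, 0.75, 0.95, 0.45, 0.55,
    "mci_neg",     4.0,  9L, 0.55, 0.08, 0.85, 1.15, 0.08, 0.75, 0.95, 0.45, 0.45,
    "mci_pos",     4.0,  9L, 0.55, 0.08, 0.80, 1.45, 0.10, 0.70, 0.90, 0.50, 0.70
  )
}

default_param_sds <- function() {
  c(k = 0.12, g2 = 0.18, beta = 0.08, g3 = 0.15, m3 = 0.15,
    sigma = 0.10, nu = 0.10)
}

## truncation bounds keeping simulated behaviour physical
param_bounds <- function() {
  list(
    lower = c(k = 1e-3, g2 = 1e-3, beta = -0.5, g3 = -0.5, m3 = -0.5,
              sigma = 1e-3, nu = 1e-3),
    upper = c(k = 3, g2 = 3, beta = 1, g3 = 2, m3 = 2, sigma = 2, nu = pi)
  )
}

#' Specify a synthetic cohort
#'
#' @param group one of `"young"`, `"elderly"`, `"mci_unknown"`,
#'   `"mci_neg"`, `"mci_pos"`; selects the preset row of
#'   [glampi_presets()].
#' @param n_participants number of participants to simulate.
#' @param rng_seed integer seed; the cohort is fully reproducible from it.
#' @param trials_per_condition trials in each of the three inbound
#'   conditions (spread over three environments); must be at least 7.
#' @param arena_side side of the square tracking area (m).
#' @param param_means named numeric vector over the seven GLAMPI
#'   parameters: group-level means of the per-participant draws.
#' @param param_sds matching SDs (draws are truncated at physical bounds).
#' @param speed_mean,speed_sd mean and SD of the per-trial constant
#'   outbound walking speed (m/s, lognormal across trials).
#' @param sample_rate head-tracking rate (Hz).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(group = c("elderly", "young", "mci_unknown",
                                  "mci_neg", "mci_pos"),
                        n_participants, rng_seed = 1L,
                        trials_per_condition = NULL, arena_side = NULL,
                        param_means = NULL, param_sds = default_param_sds(),
                        speed_mean = NULL, speed_sd = NULL,
                        sample_rate = 10) {
  group <- match.arg(group)
  preset <- glampi_presets()[glampi_presets()$group == group, ]
  if (is.null(trials_per_condition)) trials_per_condition <- preset$trials_per_condition
  if (is.null(arena_side)) arena_side <- preset$arena_side
  if (is.null(speed_mean)) speed_mean <- preset$speed_mean
  if (is.null(speed_sd)) speed_sd <- preset$speed_sd
  if (is.null(param_means)) {
    param_means <- unlist(preset[param_names()])
    names(param_means) <- param_names()
  }
  param_means <- param_means[param_names()]
  param_sds <- param_sds[param_names()]
  stopifnot(
    arena_side > 0, trials_per_condition >= 7, n_participants >= 1,
    speed_mean > 0, param_means[["sigma"]] > 0, param_means[["nu"]] > 0,
    all(is.finite(param_means)), all(param_sds >= 0), sample_rate > 0
  )
  structure(
    list(
      group = group, n_participants = as.integer(n_participants),
      trials_per_condition = as.integer(trials_per_condition),
      arena_side = arena_side, param_means = param_means,
      param_sds = param_sds, speed_mean = speed_mean, speed_sd = speed_sd,
      sample_rate = sample_rate, rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_spec"
  )
}

#' Generate one pseudo-random triangle inside a square arena
#'
#' The first cone is placed near the corner farthest from the previous
#' trial's endpoint (or near a random corner), and cones 2 and 3 near the
#' two arena sides opposite that corner, maximising the walking space.
#' "Near" means within 25% of the arena side of the target corner/side.
#' Layouts with cone2--cone3 separation below `min_sep` are rejected and
#' redrawn.
#'
#' @param arena_side side of the square arena (m), at least 2.
#' @param prev_point optional length-2 endpoint of the previous trial.
#' @param min_sep minimum cone2--cone3 separation (m).
#' @param margin_frac proximity tolerance as a fraction of the arena side.
#' @param max_attempts rejection-sampling budget before failing.
#' @return List with `cone1`, `cone2`, `cone3` (length-2, metres).
#' @export
generate_triangle <- function(arena_side, prev_point = NULL, min_sep = 1,
                              margin_frac = 0.25, max_attempts = 100L) {
  if (arena_side < 2) stop("arena_side must be at least 2 m")
  s <- arena_side
  corners <- rbind(c(0, 0), c(s, 0), c(0, s), c(s, s))
  if (is.null(prev_point)) {
    corner <- corners[sample.int(4, 1), ]
  } else {
    d2 <- rowSums(sweep(corners, 2, prev_point)^2)
    corner <- corners[which.max(d2), ]
  }
  m <- margin_frac * s
  # coordinate band within `m` of the target corner along each axis
  near <- function(at) if (at == 0) stats::runif(1, 0, m) else stats::runif(1, s - m, s)
  for (attempt in seq_len(max_attempts)) {
    cone1 <- c(near(corner[1]), near(corner[2]))
    # the two sides opposite the corner: x = s - corner_x and y = s - corner_y
    on_far_x <- c(near(s - corner[1]), stats::runif(1, 0, s))
    on_far_y <- c(stats::runif(1, 0, s), near(s - corner[2]))
    if (stats::runif(1) < 0.5) {
      cone2 <- on_far_x; cone3 <- on_far_y
    } else {
      cone2 <- on_far_y; cone3 <- on_far_x
    }
    sep <- sqrt(sum((cone2 - cone3)^2))
    l1 <- sqrt(sum((cone2 - cone1)^2))
    l2 <- sep
    if (sep >= min_sep && l1 > 0.5) {
      return(list(cone1 = cone1, cone2 = cone2, cone3 = cone3))
    }
  }
  stop("could not place cones after ", max_attempts,
       " attempts; arena/constraint combination infeasible")
}

#' Simulate the guided outbound walk of one trial
#'
#' Constant-speed piecewise-linear walking along cone1 -> cone2 -> cone3,
#' sampled at the tracking rate, with head orientation quaternions facing
#' the walking direction at a configurable downward pitch.
#'
#' @param layout triangle layout from [generate_triangle()].
#' @param speed constant walking speed (m/s), > 0.
#' @param sample_rate tracking rate (Hz).
#' @param pitch downward head pitch in radians.
#' @param height headset height above the ground (m).
#' @return List with `tracking` (tibble `t, x, y, z, qw, qx, qy, qz`),
#'   leg durations `T1`, `T2` and cone arrival times `t_cone2`, `t_cone3`.
#' @export
simulate_outbound <- function(layout, speed, sample_rate = 10,
                              pitch = 0, height = 1.7) {
  stopifnot(speed > 0)
  l1 <- sqrt(sum((layout$cone2 - layout$cone1)^2))
  l2 <- sqrt(sum((layout$cone3 - layout$cone2)^2))
  T1 <- l1 / speed
  T2 <- l2 / speed
  t <- seq(0, T1 + T2, by = 1 / sample_rate)
  u1 <- (layout$cone2 - layout$cone1) / l1
  u2 <- (layout$cone3 - layout$cone2) / l2
  on1 <- t <= T1
  pos <- matrix(NA_real_, length(t), 2)
  pos[on1, ] <- rep(layout$cone1, each = sum(on1)) + speed * t[on1] %o% u1
  pos[!on1, ] <- rep(layout$cone2, each = sum(!on1)) + speed * (t[!on1] - T1) %o% u2
  q1 <- quat_yaw_pitch(atan2(u1[2], u1[1]), pitch)
  q2 <- quat_yaw_pitch(atan2(u2[2], u2[1]), pitch)
  q <- matrix(NA_real_, length(t), 4)
  q[on1, ] <- matrix(q1, sum(on1), 4, byrow = TRUE)
  q[!on1, ] <- matrix(q2, sum(!on1), 4, byrow = TRUE)
  list(
    tracking = tibble::tibble(
      t = t, x = pos[, 1], y = pos[, 2], z = height,
      qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4]
    ),
    T1 = T1, T2 = T2, t_cone2 = T1, t_cone3 = T1 + T2
  )
}

## true egocentric geometry of a layout in its own (unflipped) frame:
## magnitudes plus the turn sense (+1 left / -1 right)
layout_geometry <- function(layout) {
  v1 <- layout$cone2 - layout$cone1
  v2 <- layout$cone3 - layout$cone2
  l1 <- sqrt(sum(v1^2)); l2 <- sqrt(sum(v2^2))
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  sense <- if (cross >= 0) 1 else -1
  theta2 <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (l1 * l2))))
  # correct inbound values in the left-turn-canonical frame
  px <- l1 + l2 * cos(theta2)
  py <- l2 * sin(theta2)
  list(
    l1 = l1, l2 = l2, theta2 = theta2, sense = sense,
    correct_dist = sqrt(px^2 + py^2),
    correct_angle = wrap_2pi(atan2(-py, -px) - theta2)
  )
}

#' Simulate one inbound response from the generative model
#'
#' Draws the produced turn and distance from the GLAMPI process (encoding
#' with `k`, `g2`, `beta`; vector-addition calculation; regression-to-the-
#' mean production with `g3`, `m3`; Gaussian noise `sigma`, `nu`) and
#' converts them to a ground-plane endpoint walked from cone 3. If the
#' straight inbound ray leaves the arena before the drawn distance is
#' covered, the trial is marked out-of-bound and terminated 0.3 m past the
#' boundary crossing (the point at which the in-task warning stops the
#' participant).
#'
#' The calculation stage uses the exact geometric (vector-addition) inbound
#' angle, so that with optimal parameters and zero noise the response is
#' exactly the first cone.
#'
#' @param layout triangle layout (original arena coordinates).
#' @param params [glampi_params()] vector of the simulated participant.
#' @param T1,T2 outbound leg durations (s).
#' @param session list with `lbar_r`, `thetabar_r`: session means of the
#'   correct inbound distance/angle for this participant-condition.
#' @param arena_side arena side (m), for the out-of-bound rule.
#' @return List with `response` (length-2 or `NULL` if out-of-bound),
#'   `oob` flag, `oob_point`, and the drawn `l3`, `theta3`.
#' @export
simulate_inbound <- function(layout, params, T1, T2, session, arena_side) {
  p <- unclass(params)
  geo <- layout_geometry(layout)
  enc <- encode_distances(geo$l1, geo$l2, T1, T2, k = p[["k"]], beta = p[["beta"]])
  th2p <- encode_angle(geo$theta2, p[["g2"]])
  calc <- calculate_inbound(enc$l1p, enc$l2p, th2p, method = "geometric")
  prod <- produce_inbound(calc$h, calc$alpha, g3 = p[["g3"]], m3 = p[["m3"]],
                          lbar_r = session$lbar_r, thetabar_r = session$thetabar_r)
  l3 <- max(stats::rnorm(1, prod$l3p, p[["sigma"]]), 0)
  theta3 <- stats::rnorm(1, prod$theta3p, p[["nu"]])
  u0 <- (layout$cone3 - layout$cone2) / geo$l2
  ang <- geo$sense * theta3   # mirror the turn back for right-turn trials
  u <- c(cos(ang) * u0[1] - sin(ang) * u0[2],
         sin(ang) * u0[1] + cos(ang) * u0[2])
  s_exit <- ray_exit_distance(layout$cone3, u, arena_side)
  if (l3 > s_exit) {
    list(response = NULL, oob = TRUE,
         oob_point = layout$cone3 + (s_exit + 0.3) * u,
         l3 = l3, theta3 = theta3)
  } else {
    list(response = layout$cone3 + l3 * u, oob = FALSE, oob_point = NULL,
         l3 = l3, theta3 = theta3)
  }
}

## truncated-normal draw by rejection (sd may be 0)
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      x <- stats::rnorm(1, mean, sd)
      if (x >= lower && x <= upper) break
    }
    out[i] <- x
  }
  out
}

draw_participant_params <- function(means, sds) {
  b <- param_bounds()
  p <- vapply(param_names(), function(nm) {
    rtrunc_norm(1, means[[nm]], sds[[nm]], b$lower[[nm]], b$upper[[nm]])
  }, numeric(1))
  glampi_params(k = p[["k"]], g2 = p[["g2"]], beta = p[["beta"]],
                g3 = p[["g3"]], m3 = p[["m3"]],
                sigma = p[["sigma"]], nu = p[["nu"]])
}

pi_conditions <- function() c("no_change", "reduced_flow", "reduced_cues")

#' Generate a full synthetic cohort in the raw trial format
#'
#' For each participant, GLAMPI parameters are drawn from the cohort's
#' truncated-normal distributions, pseudo-random triangles are laid out
#' sequentially (the first cone near the corner farthest from the previous
#' trial's goal), session means of the correct inbound distance/angle are
#' computed per condition from the layouts, and responses are simulated
#' from the generative process, including out-of-bound truncation. Each
#' participant draws from an independent seed stream derived from
#' `spec$rng_seed`, so cohorts are byte-identical across runs.
#'
#' @param spec a [cohort_spec()].
#' @param with_tracking also synthesise 10 Hz head-tracking series
#'   (needed only for speed/pitch reconstruction; slower).
#' @param session_scope scope over which the regression-to-the-mean session
#'   means are computed: per `"condition"` (default, the model's
#'   definition) or per `"participant"` (all trials pooled).
#' @param pitch downward head pitch in radians for the tracking series.
#' @return Object of class `glampi_cohort`: list with tibbles `trials`,
#'   `tracking` (or `NULL`), `params` (the true generating parameters) and
#'   the `spec`.
#' @export
generate_cohort <- function(spec, with_tracking = FALSE,
                            session_scope = c("condition", "participant"),
                            pitch = 0.25) {
  stopifnot(inherits(spec, "cohort_spec"))
  session_scope <- match.arg(session_scope)
  conds <- pi_conditions()
  sdl <- sqrt(log(1 + (spec$speed_sd / spec$speed_mean)^2))
  mnl <- log(spec$speed_mean) - sdl^2 / 2

  all_trials <- vector("list", spec$n_participants)
  all_track <- vector("list", spec$n_participants)
  all_params <- vector("list", spec$n_participants)

  for (i in seq_len(spec$n_participants)) {
    pid <- sprintf("%s_%03d", spec$group, i)
    set.seed((spec$rng_seed * 1009L + i) %% .Machine$integer.max)
    params <- draw_participant_params(spec$param_means, spec$param_sds)

    # trial plan: conditions spread over three environment blocks
    plan <- do.call(rbind, lapply(conds, function(cd) {
      data.frame(condition = cd,
                 environment = rep(1:3, length.out = spec$trials_per_condition))
    }))
    plan <- plan[order(plan$environment, plan$condition), ]
    n_tr <- nrow(plan)

    # lay out all triangles first (session means need the full layout set);
    # the previous trial's goal (cone 1) stands in for its endpoint
    layouts <- vector("list", n_tr)
    prev <- c(spec$arena_side / 2, spec$arena_side / 2)
    for (j in seq_len(n_tr)) {
      layouts[[j]] <- generate_triangle(spec$arena_side, prev_point = prev)
      prev <- layouts[[j]]$cone1
    }
    geos <- lapply(layouts, layout_geometry)
    cd_all <- vapply(geos, `[[`, numeric(1), "correct_dist")
    ca_all <- vapply(geos, `[[`, numeric(1), "correct_angle")
    sess_for <- function(j) {
      idx <- if (session_scope == "condition") {
        plan$condition == plan$condition[j]
      } else rep(TRUE, n_tr)
      list(lbar_r = mean(cd_all[idx]), thetabar_r = mean(ca_all[idx]))
    }

    speeds <- stats::rlnorm(n_tr, mnl, sdl)
    clock <- 0
    rows <- vector("list", n_tr)
    tracks <- if (with_tracking) vector("list", n_tr) else NULL
    for (j in seq_len(n_tr)) {
      ly <- layouts[[j]]; geo <- geos[[j]]
      T1 <- geo$l1 / speeds[j]; T2 <- geo$l2 / speeds[j]
      t_cone1 <- clock + 3
      t_cone2 <- t_cone1 + T1
      t_cone3 <- t_cone2 + T2
      inb <- simulate_inbound(ly, params, T1, T2, sess_for(j), spec$arena_side)
      t_resp <- t_cone3 + 2 + inb$l3 / speeds[j]
      clock <- t_resp
      rows[[j]] <- tibble::tibble(
        participant_id = pid, group = spec$group,
        environment = plan$environment[j], condition = plan$condition[j],
        trial_index = j,
        c1x = ly$cone1[1], c1y = ly$cone1[2],
        c2x = ly$cone2[1], c2y = ly$cone2[2],
        c3x = ly$cone3[1], c3y = ly$cone3[2],
        resp_x = if (inb$oob) NA_real_ else inb$response[1],
        resp_y = if (inb$oob) NA_real_ else inb$response[2],
        oob = inb$oob,
        oob_x = if (inb$oob) inb$oob_point[1] else NA_real_,
        oob_y = if (inb$oob) inb$oob_point[2] else NA_real_,
        t_cone1 = t_cone1, t_cone2 = t_cone2, t_cone3 = t_cone3,
        t_response = t_resp
      )
      if (with_tracking) {
        ob <- simulate_outbound(ly, speeds[j], spec$sample_rate, pitch = pitch)
        tr <- ob$tracking
        tr$t <- tr$t + t_cone1
        tr <- tibble::add_column(tr, participant_id = pid, trial_index = j,
                                 .before = 1)
        tracks[[j]] <- tr
      }
    }
    all_trials[[i]] <- dplyr::bind_rows(rows)
    if (with_tracking) all_track[[i]] <- dplyr::bind_rows(tracks)
    all_params[[i]] <- tibble::tibble(
      participant_id = pid, group = spec$group,
      !!!as.list(unclass(params))
    )
  }

  structure(
    list(
      trials = dplyr::bind_rows(all_trials),
      tracking = if (with_tracking) dplyr::bind_rows(all_track) else NULL,
      params = dplyr::bind_rows(all_params),
      spec = spec
    ),
    class = "glampi_cohort"
  )
}

#' Write a cohort to disk in the raw-file dialect
#'
#' Writes `trials.csv`, `tracking.csv` (if present) and a
#' `true_params.json` sidecar of the generating parameters (for recovery
#' tests). [read_cohort()] reads the same dialect back.
#'
#' @param cohort a `glampi_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  if (!is.null(cohort$tracking)) {
    utils::write.csv(cohort$tracking, file.path(dir, "tracking.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(cohort$params, file.path(dir, "true_params.json"),
                       digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `trials.csv` (and optionally
#'   `tracking.csv`, `true_params.json`).
#' @return A `glampi_cohort` (without a spec).
#' @export
read_cohort <- function(dir) {
  trials <- tibble::as_tibble(utils::read.csv(file.path(dir, "trials.csv")))
  tr_path <- file.path(dir, "tracking.csv")
  pj_path <- file.path(dir, "true_params.json")
  structure(
    list(
      trials = trials,
      tracking = if (file.exists(tr_path))
        tibble::as_tibble(utils::read.csv(tr_path)) else NULL,
      params = if (file.exists(pj_path))
        tibble::as_tibble(jsonlite::fromJSON(pj_path)) else NULL,
      spec = NULL
    ),
    class = "glampi_cohort"
  )
}
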