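#' Standardise raw trials to the left-turn-canonical frame
#'
#' Each trial is rigidly transformed so that cone 1 sits at the origin and
#' the first outbound leg lies along the positive x axis; whenever the
#' outbound turn is rightward (clockwise) the whole trial is mirrored so
#' the second leg points into the upper half-plane (quadrant II sense).
#' The response (or boundary-hit) point is transformed identically. The
#' produced turn `theta3` and the correct inbound distance/angle are then
#' extracted under the anticlockwise wrap convention.
#'
#' Trials flagged out-of-bound without a recorded boundary point are kept
#' but marked as tracking faults (`fault = TRUE`, angle absent); they are
#' removed by [apply_exclusions()].
#'
#' @param trials raw trial tibble in the `trials.csv` dialect of
#'   [generate_cohort()] (cone coordinates `c1x ... c3y`, `resp_x/y`,
#'   `oob`, `oob_x/y`, cone arrival times `t_cone1..t_cone3`).
#' @return Tibble with one row per trial: `l1`, `l2`, `theta2` (rad,
#'   `(0, pi]`), `T1`, `T2` (s), `l3` (m, `NA` for out-of-bound trials),
#'   `theta3` (rad, `[0, 2*pi)`), `oob`, `fault`, the correct inbound
#'   distance and angle, and the standardised endpoint `end_x`, `end_y`.
#' @export
standardize_trials <- function(trials) {
  need <- c("c1x", "c1y", "c2x", "c2y", "c3x", "c3y", "resp_x", "resp_y",
            "oob", "oob_x", "oob_y", "t_cone1", "t_cone2", "t_cone3")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols)) {
    stop("missing trial columns: ", paste(missing_cols, collapse = ", "))
  }
  v1x <- trials$c2x - trials$c1x; v1y <- trials$c2y - trials$c1y
  v2x <- trials$c3x - trials$c2x; v2y <- trials$c3y - trials$c2y
  l1 <- sqrt(v1x^2 + v1y^2)
  l2 <- sqrt(v2x^2 + v2y^2)
  if (any(l1 < 1e-9) || any(l2 < 1e-9)) {
    stop("degenerate geometry: coincident cones")
  }
  phi <- atan2(v1y, v1x)
  flip <- (v1x * v2y - v1y * v2x) < 0   # rightward (clockwise) outbound turn

  # rotate by -phi about cone1, then mirror y for right-turn trials
  std <- function(px, py) {
    dx <- px - trials$c1x; dy <- py - trials$c1y
    x <- cos(phi) * dx + sin(phi) * dy
    y <- -sin(phi) * dx + cos(phi) * dy
    y[flip] <- -y[flip]
    list(x = x, y = y)
  }
  c2 <- std(trials$c2x, trials$c2y)
  c3 <- std(trials$c3x, trials$c3y)
  ex <- ifelse(trials$oob, trials$oob_x, trials$resp_x)
  ey <- ifelse(trials$oob, trials$oob_y, trials$resp_y)
  fault <- trials$oob & (is.na(ex) | is.na(ey))
  e <- std(ex, ey)

  theta2 <- atan2(c3$y - c2$y, c3$x - c2$x)   # in [0, pi] after flipping
  hx <- c3$x - c2$x; hy <- c3$y - c2$y
  dx <- e$x - c3$x; dy <- e$y - c3$y
  dlen <- sqrt(dx^2 + dy^2)
  theta3 <- wrap_2pi(atan2(hx * dy - hy * dx, hx * dx + hy * dy))
  theta3[fault | dlen < 1e-12] <- NA_real_
  l3 <- ifelse(trials$oob, NA_real_, dlen)

  correct_dist <- sqrt(c3$x^2 + c3$y^2)
  theta_correct <- wrap_2pi(atan2(hx * (-c3$y) - hy * (-c3$x),
                                  hx * (-c3$x) + hy * (-c3$y)))

  keep <- intersect(c("participant_id", "group", "environment", "condition",
                      "trial_index"), names(trials))
  out <- tibble::as_tibble(trials[keep])
  out$l1 <- l1
  out$l2 <- l2
  out$theta2 <- theta2
  out$T1 <- trials$t_cone2 - trials$t_cone1
  out$T2 <- trials$t_cone3 - trials$t_cone2
  out$l3 <- l3
  out$theta3 <- theta3
  out$oob <- trials$oob
  out$fault <- fault
  out$correct_dist <- correct_dist
  out$correct_angle <- theta_correct
  out$end_x <- e$x
  out$end_y <- e$y
  out
}

#' Apply the trial and cell exclusion rules
#'
#' Per trial, in priority order: out-of-bound trials without a recorded
#' boundary point are dropped as `tracking_fault`; trials whose inbound
#' path terminated within `short_response` of cone 3 (straight-line
#' distance) are dropped as `short_response`; trials whose inbound
#' trajectory re-enters within `retrace_radius` of cone 2 (a proxy for
#' retracing the outbound path, applied only when raw trials and tracking
#' data are supplied) are dropped as `instruction_violation`. Out-of-bound
#' trials with a valid angle are retained, contributing angular (never
#' distance) information. Finally, participant-condition cells with fewer
#' than `min_trials` usable trials are dropped entirely.
#'
#' @param std standardised trials from [standardize_trials()].
#' @param raw optional raw trial tibble (for the retrace rule geometry).
#' @param tracking optional tracking tibble with inbound samples.
#' @param short_response minimum inbound termination distance (m).
#' @param min_trials minimum usable trials per participant-condition cell
#'   (the number of model parameters).
#' @param retrace_radius radius around cone 2 for the retrace proxy (m).
#' @return List with `trials` (the kept rows) and `report`: per-trial
#'   exclusions with reasons, dropped cells, and counts by group.
#' @export
apply_exclusions <- function(std, raw = NULL, tracking = NULL,
                             short_response = 0.5, min_trials = 7,
                             retrace_radius = 0.3) {
  reason <- rep(NA_character_, nrow(std))
  reason[std$fault] <- "tracking_fault"
  dlen <- sqrt((std$end_x - (std$l1 + std$l2 * cos(std$theta2)))^2 +
               (std$end_y - std$l2 * sin(std$theta2))^2)
  short <- !std$fault & (dlen < short_response | is.na(std$theta3))
  reason[is.na(reason) & short] <- "short_response"

  if (!is.null(raw) && !is.null(tracking)) {
    key <- paste(std$participant_id, std$trial_index)
    rkey <- paste(raw$participant_id, raw$trial_index)
    tkey <- paste(tracking$participant_id, tracking$trial_index)
    for (i in which(is.na(reason))) {
      ri <- match(key[i], rkey)
      if (is.na(ri)) next
      samp <- tracking[tkey == key[i] & tracking$t > raw$t_cone3[ri], , drop = FALSE]
      if (nrow(samp) == 0) next
      d2 <- (samp$x - raw$c2x[ri])^2 + (samp$y - raw$c2y[ri])^2
      if (min(d2) < retrace_radius^2) reason[i] <- "instruction_violation"
    }
  }

  usable <- is.na(reason)
  cell <- paste(std$participant_id, std$condition, sep = "\r")
  n_usable <- tapply(usable, cell, sum)
  bad_cells <- names(n_usable)[n_usable < min_trials]
  cell_drop <- usable & cell %in% bad_cells
  kept <- std[usable & !cell_drop, , drop = FALSE]

  trial_excl <- tibble::tibble(
    participant_id = std$participant_id[!usable],
    group = if ("group" %in% names(std)) std$group[!usable] else NA_character_,
    condition = std$condition[!usable],
    trial_index = std$trial_index[!usable],
    reason = reason[!usable]
  )
  cells <- tibble::tibble(
    participant_id = sub("\r.*", "", bad_cells),
    condition = sub(".*\r", "", bad_cells),
    n_usable = as.integer(n_usable[bad_cells])
  )
  counts <- dplyr::count(trial_excl, group, reason, name = "n_trials")
  list(
    trials = kept,
    report = list(trial_exclusions = trial_excl, cell_exclusions = cells,
                  counts_by_group = counts)
  )
}

#' Reconstruct the mean moving speed from a tracking series
#'
#' Instantaneous speeds are smoothed by an exponential moving average
#' \eqn{s_i = \alpha s_{i-1} + (1-\alpha) \|x_i - x_{i-1}\| / (t_i - t_{i-1})}
#' with `alpha = 0.9` (initialised at the first finite instantaneous
#' speed), then convolved with a Gaussian kernel of SD `kernel_sd` seconds
#' (truncated at 3 SD, reflected edges). The mean is taken over samples
#' faster than `stationary_threshold`, excluding a 1 s start-up burn-in.
#'
#' @param tracking tibble with columns `t`, `x`, `y`, `z`.
#' @param t_start,t_end optional bounds restricting to the outbound
#'   interval (cone 1 to cone 3 arrival).
#' @param alpha exponential moving-average weight.
#' @param kernel_sd Gaussian kernel SD in seconds.
#' @param stationary_threshold speed threshold (m/s) below which samples
#'   are treated as stationary and excluded.
#' @param burn_in initial interval (s) excluded from the mean.
#' @return List with `mean` (m/s, `NA` if every sample is stationary),
#'   `stationary` flag, and the smoothed series (`t`, `speed`).
#' @export
reconstruct_speed <- function(tracking, t_start = NULL, t_end = NULL,
                              alpha = 0.9, kernel_sd = 1,
                              stationary_threshold = 0.2, burn_in = 1) {
  tr <- tracking
  if (!is.null(t_start)) tr <- tr[tr$t >= t_start, , drop = FALSE]
  if (!is.null(t_end)) tr <- tr[tr$t <= t_end, , drop = FALSE]
  if (nrow(tr) < 2) stop("need at least two tracking samples in the interval")
  dt <- diff(tr$t)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2 + diff(tr$z)^2)
  v <- step / dt
  # recursive EMA with s_1 = v_1
  s <- as.numeric(stats::filter((1 - alpha) * v, alpha,
                                method = "recursive", init = v[1]))
  # Gaussian smoothing, kernel SD in samples, reflected edges
  sd_n <- kernel_sd / stats::median(dt)
  hw <- max(1L, ceiling(3 * sd_n))
  kern <- stats::dnorm(seq(-hw, hw), sd = sd_n)
  kern <- kern / sum(kern)
  n <- length(s)
  pad <- c(s[pmin(hw, n):1], s, s[n:pmax(1, n - hw + 1)])
  sm <- as.numeric(stats::filter(pad, kern, sides = 2))
  sm <- sm[(hw + 1):(hw + n)]
  tt <- tr$t[-1]
  sel <- sm > stationary_threshold & (tt - tr$t[1]) > burn_in
  sel[is.na(sel)] <- FALSE
  if (!any(sel)) {
    return(list(mean = NA_real_, stationary = TRUE, t = tt, speed = sm))
  }
  list(mean = mean(sm[sel]), stationary = FALSE, t = tt, speed = sm)
}

#' Mean head pitch from orientation quaternions
#'
#' The pitch of a sample is the angle between the head's forward vector
#' (the rotated `+x` axis) and the world up axis (`+z`): 90 degrees is
#' level, larger values tilt towards the ground. Typically evaluated
#' between the cone 2 and cone 3 arrival timestamps to isolate posture on
#' the outbound turn.
#'
#' @param tracking tibble with quaternion columns `qw`, `qx`, `qy`, `qz`.
#' @param t_from,t_to optional time bounds.
#' @return Mean pitch in degrees.
#' @export
head_pitch <- function(tracking, t_from = NULL, t_to = NULL) {
  tr <- tracking
  if (!is.null(t_from)) tr <- tr[tr$t >= t_from, , drop = FALSE]
  if (!is.null(t_to)) tr <- tr[tr$t <= t_to, , drop = FALSE]
  if (nrow(tr) < 1) stop("no tracking samples in the interval")
  fwd <- quat_rotate(as.matrix(tr[, c("qw", "qx", "qy", "qz")]), c(1, 0, 0))
  ang <- acos(pmin(1, pmax(-1, fwd[, 3])))   # angle between forward and up
  mean(ang * 180 / pi)
}
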