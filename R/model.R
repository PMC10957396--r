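#' Construct a GLAMPI parameter vector
#'
#' The generative linear-angular model of path integration has seven
#' parameters: a speed gain `k` and angular gain `g2` (encoding), a leak
#' rate `beta` (1/s) acting on the remembered outbound distances
#' (calculation), regression-to-the-mean slopes `m3` (distance) and `g3`
#' (angle) (production), and Gaussian noise SDs `sigma` (m) and `nu` (rad).
#' The no-error values are `k = 1, g2 = 1, beta = 0, g3 = 1, m3 = 1`.
#'
#' @param k speed gain (dimensionless).
#' @param g2 angular encoding gain.
#' @param beta leak / forgetting rate in 1/s; negative values represent
#'   growth of the remembered distance.
#' @param g3 angular production slope.
#' @param m3 distance production slope.
#' @param sigma distance noise SD in metres (>= 0).
#' @param nu angular noise SD in radians (>= 0).
#' @return Named numeric vector of class `glampi_params`.
#' @export
glampi_params <- function(k = 1, g2 = 1, beta = 0, g3 = 1, m3 = 1,
                          sigma = 0, nu = 0) {
  p <- c(k = k, g2 = g2, beta = beta, g3 = g3, m3 = m3, sigma = sigma, nu = nu)
  if (!all(is.finite(p))) stop("all GLAMPI parameters must be finite")
  if (sigma < 0 || nu < 0) stop("sigma and nu must be non-negative")
  structure(p, class = "glampi_params")
}

#' @export
print.glampi_params <- function(x, ...) {
  cat("GLAMPI parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}

param_names <- function() c("k", "g2", "beta", "g3", "m3", "sigma", "nu")

## (1 - exp(-b T)) / (b T), evaluated by its analytic limit near b T = 0 so
## the encoder is continuous at beta = 0
decay_factor <- function(beta, T) {
  x <- beta * T
  out <- -expm1(-x) / x
  small <- abs(x) < 1e-8
  if (any(small)) out[small] <- 1 - x[small] / 2 + x[small]^2 / 6
  out
}

#' Leaky-integrator encoding of the two outbound leg lengths
#'
#' Walking speed is integrated by a leaky integrator
#' \eqn{dl'/dt = -\beta l' + k v(t)}. With constant speed on each leg this
#' has the closed form
#' \deqn{l_2' = l_2 k (1 - e^{-\beta T_2}) / (\beta T_2),}
#' \deqn{l_1' = l_1 k (1 - e^{-\beta T_1}) / (\beta T_1) \, e^{-\beta T_2},}
#' the extra decay on the first leg reflecting that its memory keeps leaking
#' while the second leg is walked. The \eqn{\beta \to 0} limit is evaluated
#' analytically (never as 0/0), so the encoder is continuous at `beta = 0`
#' where it reduces to `k * l`.
#'
#' @param l1,l2 actual leg lengths (m).
#' @param T1,T2 time spent on each leg (s), > 0.
#' @param k speed gain.
#' @param beta leak rate (1/s); may be negative (growth).
#' @return List with numeric vectors `l1p` and `l2p`, the encoded lengths.
#' @export
encode_distances <- function(l1, l2, T1, T2, k = 1, beta = 0) {
  if (any(T1 <= 0) || any(T2 <= 0)) stop("leg durations must be positive")
  list(
    l1p = l1 * k * decay_factor(beta, T1) * exp(-beta * T2),
    l2p = l2 * k * decay_factor(beta, T2)
  )
}

#' Gain encoding of the outbound turn
#'
#' @param theta2 physical turning angle between the outbound legs (rad),
#'   left-turn canonical, in `(0, pi]`.
#' @param g2 angular gain; `g2 > 1` is over-estimation of the turn.
#' @return Encoded angle `g2 * theta2`.
#' @export
encode_angle <- function(theta2, g2 = 1) g2 * theta2

#' Intended inbound distance and angle from the encoded outbound path
#'
#' Vector addition of the encoded legs gives the intended inbound distance
#' \eqn{h = \sqrt{(l_1' + l_2' \cos\theta_2')^2 + (l_2' \sin\theta_2')^2}}
#' and, in the model's printed closed form, the intended egocentric turn
#' \eqn{\alpha = \pi - \asin(l_1' \sin\theta_2' / h)} (the asin argument is
#' clamped to `[-1, 1]` against floating-point overshoot). The asin form is
#' ambiguous when the encoded triangle's angle at the release vertex is
#' obtuse; an independent atan2 (vector-addition) computation is always
#' returned alongside, and trials where the two disagree are flagged.
#'
#' @param l1p,l2p encoded leg lengths (m).
#' @param theta2p encoded turn (rad).
#' @param method `"geometric"` (exact atan2 vector-addition form, the
#'   default) or `"asin"` (the printed closed form) for the returned
#'   `alpha`. The two agree except on obtuse release-vertex trials, where
#'   only the geometric form closes the triangle.
#' @return A [tibble::tibble] with columns `h`, `alpha`, `alpha_geometric`
#'   and `flagged` (TRUE where the two forms disagree by more than 1e-9).
#' @export
calculate_inbound <- function(l1p, l2p, theta2p, method = c("geometric", "asin")) {
  method <- match.arg(method)
  px <- l1p + l2p * cos(theta2p)
  py <- l2p * sin(theta2p)
  h <- sqrt(px^2 + py^2)
  if (any(h < 1e-10)) {
    stop("degenerate trial: encoded path closes on itself (h = 0)")
  }
  arg <- pmin(1, pmax(-1, l1p * sin(theta2p) / h))
  alpha_asin <- pi - asin(arg)
  # exact turn from the encoded heading (cos, sin of theta2p) to the
  # encoded return vector (-px, -py)
  alpha_geo <- wrap_2pi(atan2(-py, -px) - theta2p)
  d <- wrap_2pi(alpha_asin - alpha_geo)
  flagged <- pmin(d, 2 * pi - d) > 1e-9
  tibble::tibble(
    h = h,
    alpha = if (method == "asin") alpha_asin else alpha_geo,
    alpha_geometric = alpha_geo,
    flagged = flagged
  )
}

#' Production of the inbound response with regression to the mean
#'
#' Produced values are linear blends of the intended value and the session
#' mean of the *correct* values for that participant and condition:
#' `l3' = m3 * h + (1 - m3) * lbar_r` and
#' `theta3' = g3 * alpha + (1 - g3) * thetabar_r`.
#'
#' @param h,alpha intended inbound distance (m) and angle (rad).
#' @param g3,m3 regression slopes (1 = veridical, 0 = full regression).
#' @param lbar_r,thetabar_r session means of the correct inbound distance
#'   (m) and egocentric angle (rad).
#' @return List with vectors `l3p` and `theta3p`.
#' @export
produce_inbound <- function(h, alpha, g3 = 1, m3 = 1, lbar_r, thetabar_r) {
  list(
    l3p = m3 * h + (1 - m3) * lbar_r,
    theta3p = g3 * alpha + (1 - g3) * thetabar_r
  )
}

#' Session means of the correct inbound distance and angle
#'
#' The regression-to-the-mean terms use the means, across a participant's
#' usable trials in one condition, of the *correct* inbound distance and
#' correct egocentric inbound angle implied by the trial geometry (not the
#' produced responses).
#'
#' @param trials standardised trial table with columns `correct_dist` and
#'   `correct_angle` (see [standardize_trials()]).
#' @return List with `lbar_r` (m) and `thetabar_r` (rad).
#' @export
session_means <- function(trials) {
  stopifnot(all(c("correct_dist", "correct_angle") %in% names(trials)))
  list(
    lbar_r = mean(trials$correct_dist),
    thetabar_r = mean(trials$correct_angle)
  )
}

#' Model-predicted inbound response for each trial
#'
#' Runs encoding, calculation and production for a set of standardised
#' trials under one parameter vector.
#'
#' @param trials standardised trial table (columns `l1`, `l2`, `theta2`,
#'   `T1`, `T2`, `correct_dist`, `correct_angle`).
#' @param params [glampi_params()] vector.
#' @param session optional list with `lbar_r`, `thetabar_r`; computed from
#'   `trials` via [session_means()] when `NULL`.
#' @param angle_method passed to [calculate_inbound()].
#' @return Tibble with `l3p`, `theta3p`, `h`, `alpha`, `flagged`.
#' @export
glampi_predict <- function(trials, params, session = NULL,
                           angle_method = c("geometric", "asin")) {
  angle_method <- match.arg(angle_method)
  p <- unclass(params)
  if (is.null(session)) session <- session_means(trials)
  enc <- encode_distances(trials$l1, trials$l2, trials$T1, trials$T2,
                          k = p[["k"]], beta = p[["beta"]])
  th2p <- encode_angle(trials$theta2, p[["g2"]])
  calc <- calculate_inbound(enc$l1p, enc$l2p, th2p, method = angle_method)
  prod <- produce_inbound(calc$h, calc$alpha, g3 = p[["g3"]], m3 = p[["m3"]],
                          lbar_r = session$lbar_r, thetabar_r = session$thetabar_r)
  tibble::tibble(
    l3p = prod$l3p, theta3p = prod$theta3p,
    h = calc$h, alpha = calc$alpha, flagged = calc$flagged
  )
}

#' Negative log-likelihood of a trial set under the GLAMPI
#'
#' The observed inbound distance `l3` and turn `theta3` are modelled as
#' independent Gaussians centred on the produced values `l3'`, `theta3'`
#' with SDs `sigma` and `nu`. A complete trial contributes
#' \eqn{(l_3-l_3')^2/(2\sigma^2) + (\theta_3-\theta_3')^2/(2\nu^2) +
#' \log\sigma + \log\nu + \log 2\pi}; out-of-bound trials contribute the
#' angular terms only (their distance is unobserved, never zero). `sigma`
#' or `nu` equal to zero yields an infinite NLL (a fit-reject signal)
#' unless the corresponding residuals are exactly zero.
#'
#' @inheritParams glampi_predict
#' @param per_trial return the vector of per-trial contributions instead of
#'   the sum.
#' @return Total NLL in nats (or per-trial vector).
#' @export
glampi_nll <- function(trials, params, session = NULL, per_trial = FALSE,
                       angle_method = c("geometric", "asin")) {
  if (nrow(trials) < 1) stop("empty trial set")
  p <- unclass(params)
  pred <- glampi_predict(trials, params, session = session,
                         angle_method = match.arg(angle_method))
  sigma <- p[["sigma"]]; nu <- p[["nu"]]
  has_dist <- !trials$oob & !is.na(trials$l3)
  rd <- ifelse(has_dist, trials$l3 - pred$l3p, NA_real_)
  ra <- trials$theta3 - pred$theta3p

  gauss_nll <- function(r, s) {
    # manual Gaussian -log density so that s = 0 gives +Inf for nonzero
    # residuals instead of an error
    if (s > 0) r^2 / (2 * s^2) + log(s) + 0.5 * log(2 * pi)
    else ifelse(r == 0, Inf, Inf)  # point mass: NLL unusable either way
  }
  contrib <- gauss_nll(ra, nu)
  contrib[has_dist] <- contrib[has_dist] + gauss_nll(rd[has_dist], sigma)
  if (per_trial) contrib else sum(contrib)
}
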