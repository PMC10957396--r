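test_that("standardisation maps the worked right-turn trial to canonical form", {
  # cones (1,1), (1,3), (3,3): leg1 points +y, the outbound turn is to the
  # right, so the trial is mirrored; canonical cones (0,0), (2,0), (2,2)
  raw <- make_raw_trial(c(1, 1), c(1, 3), c(3, 3), endpoint = c(1.4, 2.2))
  std <- standardize_trials(raw)
  expect_equal(std$l1, 2)
  expect_equal(std$l2, 2)
  expect_equal(std$theta2, pi / 2, tolerance = 1e-12)
  expect_equal(std$T1, 2)
  expect_equal(std$T2, 2)
})

test_that("an already-canonical left-turn trial is unchanged", {
  raw <- make_raw_trial(c(0, 0), c(2, 0), c(2, 2), endpoint = c(0.3, 0.4))
  std <- standardize_trials(raw)
  expect_equal(std$theta2, pi / 2, tolerance = 1e-12)
  expect_equal(c(std$end_x, std$end_y), c(0.3, 0.4), tolerance = 1e-12)
})

test_that("standardisation is invariant under rigid motions and mirroring", {
  base <- make_raw_trial(c(0, 0), c(2.5, 0), c(2.5 + 2 * cos(1.9), 2 * sin(1.9)),
                         endpoint = c(0.4, -0.2))
  ref <- standardize_trials(base)
  set.seed(42)
  for (i in 1:20) {
    tr <- rigid_transform_trial(base, angle = runif(1, 0, 2 * pi),
                                shift = runif(2, -5, 5),
                                mirror = i %% 2 == 0)
    std <- standardize_trials(tr)
    expect_equal(std$l1, ref$l1, tolerance = 1e-9)
    expect_equal(std$l2, ref$l2, tolerance = 1e-9)
    expect_equal(std$theta2, ref$theta2, tolerance = 1e-9)
    expect_equal(std$theta3, ref$theta3, tolerance = 1e-9)
    expect_equal(std$l3, ref$l3, tolerance = 1e-9)
    expect_equal(std$correct_angle, ref$correct_angle, tolerance = 1e-9)
  }
})

test_that("degenerate coincident cones are rejected", {
  raw <- make_raw_trial(c(1, 1), c(1, 1), c(3, 3), endpoint = c(0, 0))
  expect_error(standardize_trials(raw), "degenerate")
})

test_that("produced turn follows the anticlockwise wrap convention", {
  # worked case: heading (-1, 1), endpoint direction (-0.8, -0.9)
  c2 <- c(2, 1); c3 <- c(1, 2)
  expect_equal(produced_turn(c2, c3, c3 + c(-0.8, -0.9)), 1.6296,
               tolerance = 1e-4)
  # perfect response on the canonical right triangle: cone1 is a 3pi/4 turn
  expect_equal(produced_turn(c(2, 0), c(2, 2), c(0, 0)), 3 * pi / 4,
               tolerance = 1e-12)
  # a clockwise deviation of 10 degrees wraps to 2pi - 10 degrees
  h <- c(0, 1)
  dir <- c(sin(10 * pi / 180), cos(10 * pi / 180))
  expect_equal(produced_turn(c(0, 0), h, h + dir), 2 * pi - 10 * pi / 180,
               tolerance = 1e-12)
  # endpoint on cone3: no direction
  expect_true(is.na(produced_turn(c(0, 0), h, h)))
})

test_that("out-of-bound angles reuse the produced-turn convention", {
  # boundary point collinear beyond cone1 gives exactly the correct angle
  c2 <- c(2, 0); c3 <- c(2, 2)
  beyond <- c3 + 1.4 * (c(0, 0) - c3)
  expect_equal(oob_angle(c2, c3, beyond), 3 * pi / 4, tolerance = 1e-12)
  expect_equal(oob_angle(c2, c3, c(-0.5, 0.3)),
               produced_turn(c2, c3, c(-0.5, 0.3)))
})

test_that("oob trials without a boundary point are tracking faults", {
  raw <- make_raw_trial(c(0, 0), c(2, 0), c(2, 2), oob = TRUE)  # no point
  std <- standardize_trials(raw)
  expect_true(std$fault)
  ex <- apply_exclusions(std, min_trials = 1)
  expect_equal(ex$report$trial_exclusions$reason, "tracking_fault")
  expect_equal(nrow(ex$trials), 0)
})

test_that("short responses are dropped and thin cells removed wholesale", {
  rows <- lapply(1:8, function(i) {
    make_raw_trial(c(0, 0), c(2.5, 0), c(2.5 + 2 * cos(2), 2 * sin(2)),
                   endpoint = c(0.3, 0.2), trial_index = i)
  })
  raw <- dplyr::bind_rows(rows)
  # trial 1 terminates 0.4 m from cone 3
  c3 <- c(2.5 + 2 * cos(2), 2 * sin(2))
  raw$resp_x[1] <- c3[1] + 0.4
  raw$resp_y[1] <- c3[2]
  std <- standardize_trials(raw)
  ex <- apply_exclusions(std)
  expect_equal(ex$report$trial_exclusions$reason, "short_response")
  expect_equal(nrow(ex$trials), 7)

  # dropping one more leaves 6 usable: the whole cell goes
  raw$resp_x[2] <- c3[1] + 0.3
  raw$resp_y[2] <- c3[2] - 0.2
  ex2 <- apply_exclusions(standardize_trials(raw))
  expect_equal(nrow(ex2$trials), 0)
  expect_equal(ex2$report$cell_exclusions$n_usable, 6L)
})

test_that("retained out-of-bound trials keep an angle but never a distance", {
  raw <- make_raw_trial(c(0, 0), c(2, 0), c(2, 2), endpoint = c(2.5, 4.3),
                        oob = TRUE)
  std <- standardize_trials(raw)
  expect_true(is.na(std$l3))
  expect_false(is.na(std$theta3))
  ex <- apply_exclusions(std, min_trials = 1)
  expect_equal(nrow(ex$trials), 1)
})

test_that("a zero-noise optimal cohort has no exclusions", {
  means <- c(k = 1, g2 = 1, beta = 0, g3 = 1, m3 = 1, sigma = 1e-3, nu = 1e-3)
  spec <- cohort_spec("elderly", 3, rng_seed = 5, param_means = means,
                      param_sds = means * 0)
  std <- standardize_trials(generate_cohort(spec)$trials)
  ex <- apply_exclusions(std)
  expect_equal(nrow(ex$report$trial_exclusions), 0)
  expect_equal(nrow(ex$trials), nrow(std))
})

test_that("speed reconstruction recovers a constant walking speed", {
  t <- seq(0, 12, by = 0.1)
  tr <- tibble::tibble(t = t, x = t * 1.0, y = 0, z = 1.7)
  sp <- reconstruct_speed(tr)
  expect_false(sp$stationary)
  expect_gt(sp$mean, 0.95)
  expect_lt(sp$mean, 1.05)
})

test_that("stationary tracks give a missing mean with a flag", {
  t <- seq(0, 5, by = 0.1)
  tr <- tibble::tibble(t = t, x = 0, y = 0, z = 1.7)
  sp <- reconstruct_speed(tr)
  expect_true(sp$stationary)
  expect_true(is.na(sp$mean))
})

test_that("stationary periods are excluded from the mean speed", {
  # 6 s standing still then 30 s at 1 m/s; the 1 s kernel smears the
  # transition, so the mean approaches 1 from below as the moving segment
  # grows
  t1 <- seq(0, 6, by = 0.1)
  t2 <- seq(6.1, 36, by = 0.1)
  tr <- tibble::tibble(
    t = c(t1, t2),
    x = c(rep(0, length(t1)), (t2 - 6) * 1.0),
    y = 0, z = 1.7
  )
  sp <- reconstruct_speed(tr)
  expect_gt(sp$mean, 0.93)
  expect_lt(sp$mean, 1.05)
})

test_that("head pitch measures the angle between gaze and the up axis", {
  tr_id <- tibble::tibble(t = 0, qw = 1, qx = 0, qy = 0, qz = 0)
  expect_equal(head_pitch(tr_id), 90)
  # 30 degrees downward tilt about the lateral axis
  q <- quat_yaw_pitch(0, 30 * pi / 180)
  tr30 <- tibble::tibble(t = 0, qw = q[1], qx = q[2], qy = q[3], qz = q[4])
  expect_equal(head_pitch(tr30), 120, tolerance = 1e-9)
  # pitch is yaw-invariant
  q2 <- quat_yaw_pitch(1.3, 30 * pi / 180)
  tr2 <- tibble::tibble(t = 0, qw = q2[1], qx = q2[2], qy = q2[3], qz = q2[4])
  expect_equal(head_pitch(tr2), 120, tolerance = 1e-9)
})

test_that("quaternion rotation agrees with an explicit rotation matrix", {
  set.seed(9)
  for (i in 1:10) {
    axis <- rnorm(3); axis <- axis / sqrt(sum(axis^2))
    ang <- runif(1, 0, 2 * pi)
    q <- c(cos(ang / 2), sin(ang / 2) * axis)
    # Rodrigues rotation oracle
    v <- c(1, 0, 0)
    vr <- v * cos(ang) + cross3(axis, v) * sin(ang) +
      axis * sum(axis * v) * (1 - cos(ang))
    expect_equal(as.numeric(quat_rotate(q, v)), vr, tolerance = 1e-9)
  }
})

test_that("zero-norm quaternions are rejected", {
  expect_error(quat_rotate(c(0, 0, 0, 0), c(1, 0, 0)), "zero-norm")
})
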