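# build a raw trial row in the trials.csv dialect from explicit geometry
make_raw_trial <- function(c1, c2, c3, endpoint = NULL, oob = FALSE,
                           speed = 1, participant_id = "p1",
                           condition = "no_change", trial_index = 1L) {
  l1 <- sqrt(sum((c2 - c1)^2))
  l2 <- sqrt(sum((c3 - c2)^2))
  tibble::tibble(
    participant_id = participant_id, group = "test", environment = 1L,
    condition = condition, trial_index = trial_index,
    c1x = c1[1], c1y = c1[2], c2x = c2[1], c2y = c2[2],
    c3x = c3[1], c3y = c3[2],
    resp_x = if (!oob && !is.null(endpoint)) endpoint[1] else NA_real_,
    resp_y = if (!oob && !is.null(endpoint)) endpoint[2] else NA_real_,
    oob = oob,
    oob_x = if (oob && !is.null(endpoint)) endpoint[1] else NA_real_,
    oob_y = if (oob && !is.null(endpoint)) endpoint[2] else NA_real_,
    t_cone1 = 0, t_cone2 = l1 / speed, t_cone3 = (l1 + l2) / speed,
    t_response = (l1 + l2) / speed + 3
  )
}

# apply a random rigid motion (plus optional mirror) to all points of a
# raw trial row
rigid_transform_trial <- function(trial, angle, shift, mirror = FALSE) {
  tf <- function(x, y) {
    if (mirror) y <- -y
    list(x = cos(angle) * x - sin(angle) * y + shift[1],
         y = sin(angle) * x + cos(angle) * y + shift[2])
  }
  for (pt in list(c("c1x", "c1y"), c("c2x", "c2y"), c("c3x", "c3y"),
                  c("resp_x", "resp_y"), c("oob_x", "oob_y"))) {
    p <- tf(trial[[pt[1]]], trial[[pt[2]]])
    trial[[pt[1]]] <- p$x
    trial[[pt[2]]] <- p$y
  }
  trial
}

# standardised-trial tibble sampled directly (fast path for likelihood and
# large-sample tests; geometry drawn uniformly, responses optional)
make_std_trials <- function(n, seed = 1) {
  set.seed(seed)
  l1 <- runif(n, 2, 4.5)
  l2 <- runif(n, 1.5, 4)
  theta2 <- runif(n, 0.6, 2.6)
  speed <- rlnorm(n, log(0.55), 0.15)
  px <- l1 + l2 * cos(theta2)
  py <- l2 * sin(theta2)
  tibble::tibble(
    participant_id = "sim", group = "sim", condition = "no_change",
    trial_index = seq_len(n),
    l1 = l1, l2 = l2, theta2 = theta2,
    T1 = l1 / speed, T2 = l2 / speed,
    l3 = NA_real_, theta3 = NA_real_, oob = FALSE, fault = FALSE,
    correct_dist = sqrt(px^2 + py^2),
    correct_angle = glampi::wrap_2pi(atan2(-py, -px) - theta2),
    end_x = NA_real_, end_y = NA_real_
  )
}

# draw model responses into a std table (vectorised forward simulation,
# independent of simulate_inbound)
simulate_responses <- function(std, params, seed = 1,
                               angle_method = "geometric") {
  set.seed(seed)
  pred <- glampi_predict(std, params, angle_method = angle_method)
  p <- unclass(params)
  std$l3 <- rnorm(nrow(std), pred$l3p, p[["sigma"]])
  std$theta3 <- rnorm(nrow(std), pred$theta3p, p[["nu"]])
  std
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# explicit pairwise Mann-Whitney AUC oracle (double loop)
auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == levels(factor(labels))[2]]
  neg <- scores[labels == levels(factor(labels))[1]]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
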