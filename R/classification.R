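#' Rank-statistic (Mann-Whitney) AUC
#'
#' The area under the empirical ROC curve of a score vector, computed as
#' the midrank Mann-Whitney statistic; ties count one half.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels binary labels (factor or logical); the positive class is
#'   the second factor level (or `TRUE`).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  pos <- as_positive(labels)
  r <- rank(scores)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must be binary")
  f == levels(f)[2]
}

## empirical ROC points (fpr, tpr), from (0,0) to (1,1)
roc_points <- function(scores, labels) {
  pos <- as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  # collapse tied scores to single threshold points
  last <- !duplicated(scores[ord][length(ord):1])[length(ord):1]
  tpr <- c(0, tp[last] / sum(pos))
  fpr <- c(0, fp[last] / sum(!pos))
  list(fpr = fpr, tpr = tpr)
}

interp_roc <- function(scores, labels, fpr_grid) {
  rp <- roc_points(scores, labels)
  stats::approx(rp$fpr, rp$tpr, xout = fpr_grid, method = "linear",
                ties = max, rule = 2)$y
}

#' Cross-validated linear-SVM ROC of a single feature
#'
#' Repeated stratified 60/40 hold-out: per repetition a linear-kernel SVM
#' is trained on 60% of each class, its decision values are calibrated to
#' posterior probabilities by a sigmoid (logistic regression on the
#' training fold; for a single-feature linear SVM the ROC is invariant to
#' this calibration), and the ROC/AUC is computed on the held-out 40%.
#' Reported are the per-repetition AUCs, their mean, the mean ROC curve on
#' a fixed grid of 101 false-positive rates, and each observation's
#' held-out posterior averaged over the repetitions in which it was in the
#' test fold.
#'
#' @param x numeric feature vector (or single-column matrix).
#' @param labels binary labels; positive class = second factor level.
#' @param reps number of hold-out repetitions.
#' @param holdout held-out fraction of each class.
#' @param seed integer seed (the whole procedure is deterministic in it).
#' @param cost SVM regularisation constant.
#' @return Object of class `svm_roc`: `aucs`, `mean_auc`, `fpr`,
#'   `mean_tpr`, `mean_posterior`, `n_redraws`, `positive`.
#' @export
svm_roc <- function(x, labels, reps = 1000, holdout = 0.4, seed = 1L,
                    cost = 1) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stop("feature values must be finite")
  pos <- as_positive(labels)
  y <- factor(ifelse(pos, "pos", "neg"), levels = c("neg", "pos"))
  n <- length(x)
  idx_pos <- which(pos); idx_neg <- which(!pos)
  if (!length(idx_pos) || !length(idx_neg)) stop("both classes must be present")
  n_tr_pos <- min(max(1L, round((1 - holdout) * length(idx_pos))), length(idx_pos) - 1L)
  n_tr_neg <- min(max(1L, round((1 - holdout) * length(idx_neg))), length(idx_neg) - 1L)

  fpr_grid <- seq(0, 1, length.out = 101)
  aucs <- numeric(reps)
  tpr_sum <- numeric(length(fpr_grid))
  post_sum <- numeric(n)
  post_n <- integer(n)
  n_redraws <- 0L

  set.seed(seed)
  for (r in seq_len(reps)) {
    repeat {
      tr <- c(sample(idx_pos, n_tr_pos), sample(idx_neg, n_tr_neg))
      te <- setdiff(seq_len(n), tr)
      if (length(unique(y[te])) == 2) break
      n_redraws <- n_redraws + 1L
    }
    score_te <- svm_posterior(x[tr], y[tr], x[te], cost = cost)
    aucs[r] <- auc_rank(score_te, y[te])
    tpr_sum <- tpr_sum + interp_roc(score_te, y[te], fpr_grid)
    post_sum[te] <- post_sum[te] + score_te
    post_n[te] <- post_n[te] + 1L
  }
  structure(
    list(
      aucs = aucs, mean_auc = mean(aucs),
      fpr = fpr_grid, mean_tpr = tpr_sum / reps,
      mean_posterior = ifelse(post_n > 0, post_sum / post_n, NA_real_),
      n_redraws = n_redraws, positive = "pos", labels = y
    ),
    class = "svm_roc"
  )
}

## train a linear SVM on (xtr, ytr), sigmoid-calibrate on the training
## fold, return posterior probabilities of the positive class on xte
svm_posterior <- function(xtr, ytr, xte, cost = 1) {
  if (stats::sd(xtr) == 0) return(rep(0.5, length(xte)))
  m <- e1071::svm(x = matrix(xtr, ncol = 1), y = ytr, kernel = "linear",
                  cost = cost, scale = FALSE)
  dv_tr <- attr(stats::predict(m, matrix(xtr, ncol = 1),
                               decision.values = TRUE), "decision.values")[, 1]
  dv_te <- attr(stats::predict(m, matrix(xte, ncol = 1),
                               decision.values = TRUE), "decision.values")[, 1]
  if (stats::sd(dv_tr) == 0) return(rep(0.5, length(xte)))
  cal <- suppressWarnings(
    stats::glm((ytr == "pos") ~ dv, family = stats::binomial(),
               data = data.frame(dv = dv_tr))
  )
  as.numeric(stats::predict(cal, newdata = data.frame(dv = dv_te),
                            type = "response"))
}

#' @export
print.svm_roc <- function(x, ...) {
  cat(sprintf("linear-SVM hold-out ROC: mean AUC %.3f over %d repetitions\n",
              x$mean_auc, length(x$aucs)))
  invisible(x)
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors evaluated on the same subjects
#' using the DeLong structural-components estimate of the variance of the
#' AUC difference, and a two-tailed z-test. When the two score vectors are
#' identical the difference and its variance are both zero and the test
#' returns `z = 0, p = 1`; constant (zero-variance) scores are flagged as
#' degenerate.
#'
#' @param scores_a,scores_b paired score vectors on the same subjects.
#' @param labels shared binary labels; positive = second factor level.
#' @return Tibble with `auc_a`, `auc_b`, `diff`, `var_diff` (plus the
#'   per-curve variance components `var_a`, `var_b`, covariance `cov_ab`),
#'   `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  pos <- as_positive(labels)
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(pos))
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stop("both classes must be present")

  comp <- function(s) {
    X <- s[pos]; Y <- s[!pos]
    psi <- outer(X, Y, function(x, y) (x > y) + 0.5 * (x == y))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  a <- comp(scores_a); b <- comp(scores_b)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  var_a <- s10[1, 1] / m + s01[1, 1] / n
  var_b <- s10[2, 2] / m + s01[2, 2] / n
  cov_ab <- s10[1, 2] / m + s01[1, 2] / n
  var_diff <- var_a + var_b - 2 * cov_ab
  dif <- a$auc - b$auc
  degenerate <- stats::sd(scores_a) == 0 || stats::sd(scores_b) == 0
  if (var_diff <= .Machine$double.eps) {
    z <- if (abs(dif) < .Machine$double.eps) 0 else Inf * sign(dif)
  } else {
    z <- dif / sqrt(var_diff)
  }
  p <- if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z))
  tibble::tibble(
    auc_a = a$auc, auc_b = b$auc, diff = dif,
    var_a = var_a, var_b = var_b, cov_ab = cov_ab, var_diff = var_diff,
    z = z, p = p, degenerate = degenerate
  )
}
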