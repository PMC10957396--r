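#' Enumerate the candidate-model lattice
#'
#' Candidate models free different subsets of the five structural
#' parameters `{k, g2, beta, m3, g3}` (masked-off parameters are fixed at
#' their no-error values `k = 1, g2 = 1, beta = 0, m3 = 1, g3 = 1`); the
#' noise SDs `sigma` and `nu` are always estimated. The lattice has all
#' `2^5 = 32` masks, ordered by free-parameter count; the empty mask is
#' the veridical-plus-noise model and the full mask is the GLAMPI.
#'
#' @return Tibble with columns `model`, logical mask columns `k`, `g2`,
#'   `beta`, `m3`, `g3`, and `n_free` (which counts `sigma` and `nu`).
#' @export
candidate_models <- function() {
  g <- expand.grid(k = c(FALSE, TRUE), g2 = c(FALSE, TRUE),
                   beta = c(FALSE, TRUE), m3 = c(FALSE, TRUE),
                   g3 = c(FALSE, TRUE))
  nm <- apply(g, 1, function(r) {
    free <- names(g)[as.logical(r)]
    if (!length(free)) "noise_only" else paste(free, collapse = "+")
  })
  out <- tibble::as_tibble(g)
  out$model <- nm
  out$n_free <- 2L + as.integer(rowSums(g))
  out <- out[order(out$n_free, out$model), c("model", "k", "g2", "beta", "m3", "g3", "n_free")]
  out
}

struct_bounds <- function() {
  list(lower = c(k = 1e-3, g2 = 1e-3, beta = -0.5, m3 = -1, g3 = -1),
       upper = c(k = 3, g2 = 3, beta = 1, m3 = 2, g3 = 2))
}

nominal_struct <- function() c(k = 1, g2 = 1, beta = 0, m3 = 1, g3 = 1)

## concentrated NLL factory: sigma and nu are profiled out in closed form
## (the MLE of a Gaussian SD given the structural parameters), then clamped
## to their bounds; the result is the same constrained optimum with a
## search space of at most 5 dimensions. The inner loop is compiled
## (conc_nll_cpp); the pure-R glampi_nll() is the reference it is tested
## against.
make_conc_nll <- function(trials, mask, session, angle_method = "geometric") {
  l1 <- as.numeric(trials$l1); l2 <- as.numeric(trials$l2)
  T1 <- as.numeric(trials$T1); T2 <- as.numeric(trials$T2)
  th2 <- as.numeric(trials$theta2)
  th3 <- as.numeric(trials$theta3)
  l3 <- as.numeric(trials$l3)
  has_d <- !trials$oob & !is.na(l3)
  l3[!has_d] <- 0
  lbar <- session$lbar_r; tbar <- session$thetabar_r
  free_idx <- which(mask)
  fixed <- nominal_struct()
  geometric <- identical(angle_method, "geometric")

  list(
    fn = function(theta) {
      p <- fixed
      p[free_idx] <- theta
      conc_nll_cpp(p, l1, l2, T1, T2, th2, th3, l3, has_d,
                   lbar, tbar, geometric)
    },
    gr = function(theta) {
      p <- fixed
      p[free_idx] <- theta
      conc_nll_grad_cpp(p, l1, l2, T1, T2, th2, th3, l3, has_d,
                        lbar, tbar, geometric)[free_idx]
    }
  )
}

## recover the profiled sigma, nu at the structural optimum
profiled_noise <- function(trials, params_struct, session, angle_method = "geometric") {
  p <- glampi_params(k = params_struct[["k"]], g2 = params_struct[["g2"]],
                     beta = params_struct[["beta"]], g3 = params_struct[["g3"]],
                     m3 = params_struct[["m3"]], sigma = 1, nu = 1)
  pred <- glampi_predict(trials, p, session = session,
                         angle_method = angle_method)
  has_d <- !trials$oob & !is.na(trials$l3)
  ra <- trials$theta3 - pred$theta3p
  nu <- min(max(sqrt(mean(ra^2)), 1e-4), pi)
  sigma <- if (any(has_d)) {
    rd <- trials$l3[has_d] - pred$l3p[has_d]
    min(max(sqrt(mean(rd^2)), 1e-4), 3)
  } else NA_real_
  c(sigma = sigma, nu = nu)
}

#' Fit a candidate model to one participant-condition cell
#'
#' Maximum-likelihood estimation by seeded multi-start bounded local
#' optimisation: the first start is the no-error parameter point and the
#' remaining starts are a Latin-hypercube sample of the box
#' `k, g2 in (0, 3], beta in [-0.5, 1], m3, g3 in [-1, 2]`. The noise SDs
#' are profiled out in closed form (and clamped to
#' `sigma in (1e-4, 3], nu in (1e-4, pi]`), so the numerical search runs
#' over the free structural parameters only. Deterministic given `seed`.
#'
#' @param trials standardised, exclusion-filtered trials of one
#'   participant-condition cell; at least 7 (the parameter count).
#' @param mask named logical vector over `c("k","g2","beta","m3","g3")`
#'   (see [candidate_models()]); defaults to the full GLAMPI.
#' @param n_starts number of optimisation starts (>= 1).
#' @param seed integer seed for the start sample.
#' @param min_trials refusal threshold on the trial count.
#' @param angle_method inbound-angle form, passed to the likelihood.
#' @return Object of class `glampi_fit`: estimated `params`, `nll`,
#'   `aic = 2 n_free + 2 nll`, `bic = n_free log(n_trials) + 2 nll`,
#'   counts, convergence diagnostics and the winning start index.
#' @export
fit_glampi <- function(trials, mask = NULL, n_starts = 20, seed = 1L,
                       min_trials = 7, angle_method = c("geometric", "asin")) {
  angle_method <- match.arg(angle_method)
  if (is.null(mask)) {
    mask <- c(k = TRUE, g2 = TRUE, beta = TRUE, m3 = TRUE, g3 = TRUE)
  }
  mask <- mask[c("k", "g2", "beta", "m3", "g3")]
  n_free <- 2L + sum(mask)
  n_trials <- nrow(trials)
  if (n_trials < min_trials) {
    stop("refusing to fit: ", n_trials, " trials is fewer than ", min_trials)
  }
  if (n_trials < n_free) stop("fewer trials than free parameters")
  if (all(is.na(trials$theta3))) stop("no usable angle observations")

  session <- session_means(trials)
  fns <- make_conc_nll(trials, mask, session, angle_method)
  obj <- fns$fn
  d <- sum(mask)
  b <- struct_bounds()
  lower <- b$lower[names(mask)[mask]]
  upper <- b$upper[names(mask)[mask]]

  if (d == 0L) {
    best <- list(par = numeric(0), objective = obj(numeric(0)), convergence = 0L)
    best_start <- 1L
    n_starts <- 1L
    convs <- 0L
  } else {
    starts <- matrix(nominal_struct()[names(mask)[mask]], nrow = 1)
    if (n_starts > 1) {
      lh <- local({
        set.seed(seed)
        lhs::randomLHS(n_starts - 1L, d)
      })
      starts <- rbind(starts,
                      sweep(sweep(lh, 2, upper - lower, "*"), 2, lower, "+"))
    }
    fits <- vector("list", nrow(starts))
    for (s in seq_len(nrow(starts))) {
      fits[[s]] <- tryCatch(
        stats::nlminb(starts[s, ], obj, gradient = fns$gr,
                      lower = lower, upper = upper,
                      control = list(iter.max = 300, eval.max = 600,
                                     rel.tol = 1e-9)),
        error = function(e) list(par = starts[s, ], objective = Inf,
                                 convergence = 1L)
      )
    }
    vals <- vapply(fits, `[[`, numeric(1), "objective")
    best_start <- which.min(vals)
    best <- fits[[best_start]]
    convs <- vapply(fits, `[[`, numeric(1), "convergence")
  }

  struct <- nominal_struct()
  struct[names(mask)[mask]] <- best$par
  noise <- profiled_noise(trials, struct, session, angle_method)
  params <- glampi_params(k = struct[["k"]], g2 = struct[["g2"]],
                          beta = struct[["beta"]], g3 = struct[["g3"]],
                          m3 = struct[["m3"]],
                          sigma = if (is.na(noise[["sigma"]])) 0 else noise[["sigma"]],
                          nu = noise[["nu"]])
  nll <- best$objective
  structure(
    list(
      params = params, mask = mask, nll = nll,
      n_trials = n_trials, n_free = n_free,
      aic = 2 * n_free + 2 * nll,
      bic = n_free * log(n_trials) + 2 * nll,
      n_starts = if (d == 0L) 1L else nrow(starts),
      best_start = best_start,
      converged = best$convergence == 0,
      n_converged = if (d == 0L) 1L else sum(convs == 0),
      session = session
    ),
    class = "glampi_fit"
  )
}

#' @export
print.glampi_fit <- function(x, ...) {
  cat("GLAMPI fit:", sum(x$mask), "free structural parameters,",
      x$n_trials, "trials\n")
  print(round(unclass(x$params), 4))
  cat(sprintf("NLL %.3f  AIC %.3f  BIC %.3f  converged %s\n",
              x$nll, x$aic, x$bic, x$converged))
  invisible(x)
}

#' Fit a whole preprocessed dataset
#'
#' Fits each participant-condition cell independently (the per-condition
#' parameter comparisons require no sharing across conditions), for the
#' GLAMPI alone or the whole candidate lattice, and returns a tidy table.
#'
#' @param std standardised, exclusion-filtered trial table.
#' @param candidates `"glampi"` (full model only), `"all"` (the 32-model
#'   lattice), or a tibble in the format of [candidate_models()].
#' @param n_starts,seed,min_trials,angle_method passed to [fit_glampi()];
#'   each cell gets a distinct seed derived from `seed`.
#' @param pool_conditions fit one cell per participant, pooling all
#'   conditions (used by the model-selection experiment).
#' @return Tibble with one row per cell x candidate: the seven estimates,
#'   `nll`, `aic`, `bic`, counts and convergence flags.
#' @export
fit_cohort <- function(std, candidates = "glampi", n_starts = 20, seed = 1L,
                       min_trials = 7, pool_conditions = FALSE,
                       angle_method = "geometric") {
  cand <- if (is.character(candidates)) {
    if (candidates == "glampi") {
      dplyr::filter(candidate_models(), model == "k+g2+beta+m3+g3")
    } else if (candidates == "all") {
      candidate_models()
    } else stop("unknown candidates spec")
  } else candidates

  cell_key <- if (pool_conditions) std$participant_id
              else paste(std$participant_id, std$condition, sep = "\r")
  cells <- split(seq_len(nrow(std)), cell_key)
  cells <- cells[order(names(cells))]

  rows <- list()
  cell_i <- 0L
  for (cl in cells) {
    cell_i <- cell_i + 1L
    tr <- std[cl, , drop = FALSE]
    for (ci in seq_len(nrow(cand))) {
      mask <- unlist(cand[ci, c("k", "g2", "beta", "m3", "g3")])
      fit <- tryCatch(
        fit_glampi(tr, mask = mask, n_starts = n_starts,
                   seed = (seed + 7919L * cell_i + ci) %% .Machine$integer.max,
                   min_trials = min_trials, angle_method = angle_method),
        error = function(e) NULL
      )
      if (is.null(fit)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = tr$participant_id[1],
        group = if ("group" %in% names(tr)) tr$group[1] else NA_character_,
        condition = if (pool_conditions) "pooled" else as.character(tr$condition[1]),
        model = cand$model[ci],
        n_free = fit$n_free,
        !!!as.list(unclass(fit$params)),
        nll = fit$nll, aic = fit$aic, bic = fit$bic,
        n_trials = fit$n_trials, converged = fit$converged
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Rank candidate models by mean AIC across participants
#'
#' Computes the mean and SEM of AIC (and BIC) per candidate across cells,
#' keeping only cells fitted under every candidate (pairwise-complete
#' comparison). The winner is the lowest mean AIC; ties are broken in
#' favour of fewer free parameters.
#'
#' @param fits tidy fit table from [fit_cohort()] run with
#'   `candidates = "all"`.
#' @return Tibble of candidates ordered by mean AIC, with `rank`.
#' @export
select_model <- function(fits) {
  fits$cell <- paste(fits$participant_id, fits$condition, sep = "\r")
  n_models <- length(unique(fits$model))
  complete <- names(which(table(fits$cell) == n_models))
  kept <- fits[fits$cell %in% complete, , drop = FALSE]
  out <- kept |>
    dplyr::group_by(model, n_free) |>
    dplyr::summarise(
      mean_aic = mean(aic), sem_aic = stats::sd(aic) / sqrt(dplyr::n()),
      mean_bic = mean(bic), mean_nll = mean(nll),
      n_cells = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(mean_aic, n_free)
  out$rank <- seq_len(nrow(out))
  out
}
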