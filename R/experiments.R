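#' Parameter-recovery experiment
#'
#' Generates a cohort, runs it through standardisation, exclusions and
#' per-cell GLAMPI fitting, joins the estimates to the true generating
#' parameters, and summarises recovery: per parameter the median bias
#' (estimate minus the participant's true value, across cells) and the
#' same expressed relative to the group-level generating mean.
#'
#' @param n_participants cohort size.
#' @param group preset group label (see [glampi_presets()]).
#' @param seed integer seed.
#' @param trials_per_condition trials per condition (9 is the study's
#'   elderly/MCI count).
#' @param n_starts optimisation starts per fit.
#' @return List with `summary` (per-parameter tibble), the tidy `fits`
#'   joined to truth, and the cohort `truth` table.
#' @export
parameter_recovery <- function(n_participants = 100, group = "elderly",
                               seed = 1L, trials_per_condition = 9,
                               n_starts = 20) {
  spec <- cohort_spec(group, n_participants,
                      trials_per_condition = trials_per_condition,
                      rng_seed = seed)
  cohort <- generate_cohort(spec)
  std <- standardize_trials(cohort$trials)
  kept <- apply_exclusions(std)$trials
  fits <- fit_cohort(kept, candidates = "glampi", n_starts = n_starts,
                     seed = seed)
  truth <- cohort$params
  joined <- dplyr::inner_join(
    fits, truth, by = c("participant_id", "group"),
    suffix = c("_hat", "_true")
  )
  summ <- dplyr::bind_rows(lapply(param_names(), function(nm) {
    bias <- joined[[paste0(nm, "_hat")]] - joined[[paste0(nm, "_true")]]
    gen <- spec$param_means[[nm]]
    tibble::tibble(
      param = nm,
      generating_mean = gen,
      median_bias = stats::median(bias),
      rel_median_bias = stats::median(bias) / abs(gen),
      iqr_bias = stats::IQR(bias),
      n_cells = length(bias)
    )
  }))
  list(summary = summ, fits = joined, truth = truth, spec = spec)
}

#' Group-difference detection experiment
#'
#' Repeatedly simulates an MCI-positive-like and an MCI-negative-like
#' cohort at clinical sample sizes, fits the GLAMPI per participant-
#' condition cell, and tests the group effect on the fitted `g2` and `nu`
#' with the group x condition ANOVA. Returns the per-replicate p-values
#' and the fraction of replicates detecting each effect at alpha.
#'
#' @param n_replicates number of seeded replicates.
#' @param n_pos,n_neg group sizes (defaults near the study's MCI+ / MCI-
#'   counts).
#' @param seed integer seed; replicate r uses a seed derived from it.
#' @param alpha significance level.
#' @param n_starts optimisation starts per fit.
#' @return List with `replicates` (tibble of p-values) and `detection`
#'   (rates for `g2` and `nu`).
#' @export
group_detection_experiment <- function(n_replicates = 20, n_pos = 11,
                                       n_neg = 14, seed = 1L, alpha = 0.05,
                                       n_starts = 20) {
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    sd_r <- (seed + 104729L * r) %% .Machine$integer.max
    fits <- dplyr::bind_rows(lapply(
      list(c("mci_pos", n_pos), c("mci_neg", n_neg)),
      function(gs) {
        spec <- cohort_spec(gs[1], as.integer(gs[2]),
                            rng_seed = (sd_r + as.integer(gs[2])) %% .Machine$integer.max)
        cohort <- generate_cohort(spec)
        kept <- apply_exclusions(standardize_trials(cohort$trials))$trials
        fit_cohort(kept, candidates = "glampi", n_starts = n_starts, seed = sd_r)
      }
    ))
    p_of <- function(col) {
      an <- pi_anova(fits, response = col)
      an$anova$p[an$anova$term == "group"]
    }
    rows[[r]] <- tibble::tibble(replicate = r, p_g2 = p_of("g2"),
                                p_nu = p_of("nu"))
  }
  reps <- dplyr::bind_rows(rows)
  list(
    replicates = reps,
    detection = tibble::tibble(
      param = c("g2", "nu"),
      rate = c(mean(reps$p_g2 < alpha), mean(reps$p_nu < alpha))
    )
  )
}

#' All-sources generating configuration for the model-selection experiment
#'
#' A configuration in which every structural error source is clearly
#' active (each parameter well away from its no-error value) with small
#' between-participant spread and moderate noise. With values where some
#' parameter sits at its nominal value (as the healthy-elderly fits
#' suggest for `m3` and `beta`), the reduced model lacking it is the true
#' model and no selection procedure should prefer the full one; a
#' demonstration that AIC recovers the full model therefore requires all
#' sources present.
#'
#' @return Named list with `means` and `sds` over the seven parameters.
#' @export
all_sources_preset <- function() {
  list(
    means = c(k = 0.8, g2 = 1.3, beta = 0.2, g3 = 0.6, m3 = 0.7,
              sigma = 0.25, nu = 0.35),
    sds = c(k = 0.05, g2 = 0.05, beta = 0.05, g3 = 0.05, m3 = 0.05,
            sigma = 0.03, nu = 0.03)
  )
}

#' AIC model-selection experiment on self-generated truth
#'
#' Simulates a cohort from a known generating model, fits all 32
#' candidate models per participant (conditions pooled, 27 trials each,
#' with session means computed over the pooled trials in both generation
#' and fitting), and ranks candidates by mean AIC.
#'
#' @param truth `"full"` (the all-sources configuration,
#'   [all_sources_preset()]) or `"noise_only"` (all structural parameters
#'   at their no-error values, noise only).
#' @param n_participants cohort size.
#' @param seed integer seed.
#' @param n_starts optimisation starts per fit.
#' @return List with the candidate `ranking` (see [select_model()]) and
#'   the tidy `fits`.
#' @export
model_selection_experiment <- function(truth = c("full", "noise_only"),
                                       n_participants = 40, seed = 1L,
                                       n_starts = 20) {
  truth <- match.arg(truth)
  if (truth == "full") {
    cfg <- all_sources_preset()
  } else {
    cfg <- list(
      means = c(k = 1, g2 = 1, beta = 0, g3 = 1, m3 = 1,
                sigma = 0.3, nu = 0.4),
      sds = c(k = 0, g2 = 0, beta = 0, g3 = 0, m3 = 0, sigma = 0, nu = 0)
    )
  }
  spec <- cohort_spec("elderly", n_participants, rng_seed = seed,
                      trials_per_condition = 9, arena_side = 4.0,
                      param_means = cfg$means, param_sds = cfg$sds,
                      speed_sd = 0.15)
  cohort <- generate_cohort(spec, session_scope = "participant")
  kept <- apply_exclusions(standardize_trials(cohort$trials))$trials
  fits <- fit_cohort(kept, candidates = "all", n_starts = n_starts,
                     seed = seed, pool_conditions = TRUE)
  list(ranking = select_model(fits), fits = fits, spec = spec)
}
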