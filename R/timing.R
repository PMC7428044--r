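# Bayesian timing of malignant progression: a hierarchical Poisson-Gamma
# model for the interval between the founder cell of the high-grade
# precursor and the founder cell of the invasive carcinoma.
#
# Model, for each patient i with y_i mutations acquired on the cancer-private
# branch, at a fixed somatic mutation rate mu (mutations/year):
#   y_i ~ Poisson(theta_i),  theta_i = mu * T_i,  T_i ~ Gamma(a, b)
#   a = 1 + m*b,  b = (m + sqrt(m^2 + 4 s^2)) / (2 s^2)
#   m ~ Uniform(0, 100),  s ~ Uniform(0, 100)
# so the Gamma prior on the latent progression times T_i has mode exactly m
# and standard deviation exactly s.

#' Count mutations acquired between the high-grade precursor and the cancer
#'
#' For each patient with paired whole-exome precursor and cancer samples,
#' y is the number of sites called present (primary or secondary) in the
#' cancer sample and confidently absent (not indeterminate) in the paired
#' high-grade precursor sample. Patients whose precursor sample was
#' reclassified as cancerization (intraductal spread of the carcinoma) are
#' excluded, because no true precursor genotype is available.
#'
#' @param call_matrix Output of [build_call_matrix()].
#' @param pairs Data.frame `patient_id, precursor_id, cancer_id` (whole-exome
#'   sample ids).
#' @param exclude Patient ids to exclude (e.g. cancerization cases).
#' @return Data.frame `patient_id, y`.
#' @export
count_acquired_mutations <- function(call_matrix, pairs, exclude = character()) {
  pairs <- pairs[!(pairs$patient_id %in% exclude), , drop = FALSE]
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    cm <- call_matrix[call_matrix$patient_id == p$patient_id, ]
    canc <- cm[cm$sample_id == p$cancer_id, ]
    prec <- cm[cm$sample_id == p$precursor_id, ]
    if (nrow(canc) == 0 || nrow(prec) == 0) {
      warning("missing paired sample for patient ", p$patient_id, "; skipped")
      return(NULL)
    }
    st_prec <- prec$status[match(canc$site_id, prec$site_id)]
    y <- sum(canc$status %in% c("present_primary", "present_secondary") &
               st_prec == "absent", na.rm = TRUE)
    data.frame(patient_id = p$patient_id, y = y, stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||%
    data.frame(patient_id = character(), y = integer())
}

#' Gamma shape/rate from mode and standard deviation
#'
#' Inverts the (mode, sd) parameterization of the Gamma prior on
#' progression times: `b = (m + sqrt(m^2 + 4 s^2)) / (2 s^2)`,
#' `a = 1 + m * b`. The returned Gamma(a, b) has mode exactly `m` and
#' standard deviation exactly `s`.
#'
#' @param m Mode in years (>= 0).
#' @param s Standard deviation in years (> 0).
#' @return Named numeric vector `c(a = shape, b = rate)`.
#' @export
gamma_hyperparams <- function(m, s) {
  if (s <= 0) stop("s must be positive")
  if (m < 0) stop("m must be non-negative")
  m <- unname(m); s <- unname(s)
  b <- (m + sqrt(m^2 + 4 * s^2)) / (2 * s^2)
  c(a = 1 + m * b, b = b)
}

#' Fit the progression-timing model at a fixed mutation rate
#'
#' Markov chain Monte Carlo with exact conjugate Gibbs updates for the
#' latent times, `T_i | y_i, m, s ~ Gamma(a + y_i, b + mu)`, and random-walk
#' Metropolis updates for the hyperparameters `m` and `s` with reflection at
#' their Uniform(0, 100) bounds. Step sizes are adapted during burn-in only.
#'
#' @param y Integer vector of acquired-mutation counts, one per patient.
#' @param mu Fixed mutation rate (mutations/year).
#' @param chains,iters,burn_in MCMC schedule.
#' @param fix_hyper Optional `c(m, s)`: fix the hyperparameters (no
#'   Metropolis step); used for conjugacy checks.
#' @param seed Integer seed.
#' @param rhat_bound Convergence bound on the split-chain statistic.
#' @return List of class `timing_fit`: `mu`, `draws` (post-burn-in matrix
#'   with columns `m`, `s`, `T1..Tn`), `summary` (per-patient posterior
#'   median and 90% credible interval), `rhat`, `converged`.
#' @export
fit_timing_model <- function(y, mu, chains = 4L, iters = 20000L,
                             burn_in = 5000L, fix_hyper = NULL, seed = 1L,
                             rhat_bound = 1.01) {
  stopifnot(length(y) >= 1, all(y >= 0), mu > 0)
  n <- length(y)
  keep <- iters - burn_in
  all_draws <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, paste0("timing-chain-", ch)))
    m <- if (is.null(fix_hyper)) stats::runif(1, 0, 10) else fix_hyper[1]
    s <- if (is.null(fix_hyper)) stats::runif(1, 0.5, 10) else fix_hyper[2]
    step_m <- 1; step_s <- 1
    acc_m <- acc_s <- 0L
    draws <- matrix(NA_real_, keep, 2 + n)
    colnames(draws) <- c("m", "s", paste0("T", seq_len(n)))
    ab <- gamma_hyperparams(max(m, 0), max(s, 1e-8))
    Tvec <- stats::rgamma(n, ab["a"] + y, ab["b"] + mu)
    for (it in seq_len(iters)) {
      # Gibbs: exact conditional for each latent time
      ab <- gamma_hyperparams(m, s)
      Tvec <- stats::rgamma(n, ab["a"] + y, ab["b"] + mu)
      if (is.null(fix_hyper)) {
        # Metropolis on m with reflection at [0, 100]
        m_prop <- reflect(m + stats::rnorm(1, 0, step_m), 0, 100)
        if (log_prior_T(Tvec, m_prop, s) - log_prior_T(Tvec, m, s) >
            log(stats::runif(1))) { m <- m_prop; acc_m <- acc_m + 1L }
        s_prop <- reflect(s + stats::rnorm(1, 0, step_s), 1e-6, 100)
        if (log_prior_T(Tvec, m, s_prop) - log_prior_T(Tvec, m, s) >
            log(stats::runif(1))) { s <- s_prop; acc_s <- acc_s + 1L }
        if (it <= burn_in && it %% 200 == 0) {  # adapt during burn-in only
          step_m <- tune_step(step_m, acc_m / 200)
          step_s <- tune_step(step_s, acc_s / 200)
          acc_m <- acc_s <- 0L
        }
      }
      if (it > burn_in) draws[it - burn_in, ] <- c(m, s, Tvec)
    }
    all_draws[[ch]] <- draws
  }
  pooled <- do.call(rbind, all_draws)
  rhat <- vapply(seq_len(ncol(pooled)), function(j)
    split_rhat(lapply(all_draws, function(d) d[, j])), numeric(1))
  names(rhat) <- colnames(pooled)
  monitored <- if (is.null(fix_hyper)) rhat else rhat[-(1:2)]
  fit <- list(
    mu = mu,
    draws = pooled,
    summary = data.frame(
      patient = seq_len(n), y = y,
      posterior_median_T = apply(pooled[, -(1:2), drop = FALSE], 2,
                                 stats::median),
      ci5 = apply(pooled[, -(1:2), drop = FALSE], 2, stats::quantile,
                  probs = 0.05),
      ci95 = apply(pooled[, -(1:2), drop = FALSE], 2, stats::quantile,
                   probs = 0.95)
    ),
    rhat = rhat,
    converged = all(monitored < rhat_bound, na.rm = TRUE)
  )
  class(fit) <- "timing_fit"
  fit
}

reflect <- function(x, lo, hi) {
  while (x < lo || x > hi) {
    if (x < lo) x <- 2 * lo - x
    if (x > hi) x <- 2 * hi - x
  }
  x
}

log_prior_T <- function(Tvec, m, s) {
  if (m < 0 || m > 100 || s <= 0 || s > 100) return(-Inf)
  ab <- gamma_hyperparams(m, s)
  sum(stats::dgamma(Tvec, ab["a"], ab["b"], log = TRUE))
}

tune_step <- function(step, rate, target = 0.44) {
  step * exp(rate - target)
}

# split-chain potential scale reduction factor
split_rhat <- function(chain_list) {
  halves <- unlist(lapply(chain_list, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[(h + 1):(2 * h)])
  }), recursive = FALSE)
  mns <- vapply(halves, mean, numeric(1))
  vrs <- vapply(halves, stats::var, numeric(1))
  nh <- length(halves[[1]])
  B <- nh * stats::var(mns)
  W <- mean(vrs)
  if (W < 1e-300) return(1)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Fit the timing model across a grid of mutation rates
#'
#' The somatic mutation rate is not identifiable from a single count per
#' patient, so the model is fitted at each rate in a plausible grid
#' (default 1-10 mutations/year) and per-patient posterior medians are
#' reported per rate, together with each patient's across-grid average
#' median and the cohort mean of those averages ("average median time to
#' progression").
#'
#' @param y Acquired-mutation counts.
#' @param mu_grid Mutation rates to evaluate.
#' @param patient_ids Optional labels for output rows.
#' @param seed Integer seed.
#' @param ... Passed to [fit_timing_model()].
#' @return List: `per_mu` (data.frame `patient_id, mu, y, posterior_median_T,
#'   ci5, ci95, rhat_max`), `per_patient` (across-grid average median per
#'   patient), `cohort_average_median_T`.
#' @export
summarize_mu_grid <- function(y, mu_grid = 1:10, patient_ids = NULL,
                              seed = 1L, ...) {
  stopifnot(length(mu_grid) >= 1)
  if (is.null(patient_ids)) patient_ids <- paste0("P", seq_along(y))
  rows <- list()
  for (mu in mu_grid) {
    fit <- fit_timing_model(y, mu, seed = substream_seed(seed,
                                                         paste0("mu-", mu)), ...)
    rows[[length(rows) + 1]] <- data.frame(
      patient_id = patient_ids, mu = mu, y = y,
      posterior_median_T = fit$summary$posterior_median_T,
      ci5 = fit$summary$ci5, ci95 = fit$summary$ci95,
      rhat_max = max(fit$rhat, na.rm = TRUE),
      converged = fit$converged,
      stringsAsFactors = FALSE)
  }
  per_mu <- do.call(rbind, rows)
  per_patient <- stats::aggregate(posterior_median_T ~ patient_id, per_mu, mean)
  names(per_patient)[2] <- "mean_posterior_median_T"
  list(per_mu = per_mu,
       per_patient = per_patient,
       cohort_average_median_T = mean(per_patient$mean_posterior_median_T))
}
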