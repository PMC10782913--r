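#' Configuration for a synthetic glioma-like cohort
#'
#' Defaults emulate a two-grade cohort of the size and structure the
#' pair analysis assumes: LGG-like and GBM-like diagnosis groups,
#' regulator-target expression blocks whose pairwise Pearson
#' correlation exceeds the catalog threshold, a planted subset of
#' pairs whose within-sample ordering reverses between grades, and
#' right-censored proportional-hazards survival driven by the true
#' pair indicators.
#'
#' @param n_group1,n_group2 Samples per diagnosis group (LGG-like /
#'   GBM-like; defaults 250/250).
#' @param n_regulators Number of simulated regulators (default 10).
#' @param targets_per_regulator Targets correlated with each
#'   regulator (default 4).
#' @param rho Within-block Pearson correlation in (0,1) (default
#'   0.8, comfortably above the 0.5 catalog threshold).
#' @param n_reversed_pairs Pairs with a planted ordering reversal
#'   (default 10), spread round-robin over the regulators.
#' @param delta Reversal strength: the regulator-target mean
#'   difference is `+delta` in group 1 and `-delta` in group 2, in
#'   units of the per-gene SD (default 3; the difference SD is
#'   `sqrt(2 * (1 - rho))`, so the default makes the ordering
#'   near-deterministic within each group). Blocks containing a
#'   reversed pair additionally carry a shared grade effect of
#'   `1.5 * delta` on every member, mimicking grade-associated
#'   modules; this keeps the pooled regulator-target correlation of
#'   reversed pairs above the 0.5 catalog threshold (the reversal
#'   alone would dilute it).
#' @param betas Numeric vector of log hazard ratios for planted
#'   prognostic pairs, applied to the first `length(betas)` reversed
#'   pairs (default `c(0.8, -0.5)`).
#' @param beta_age Log hazard ratio per year of age, centered at 50
#'   (default 0, i.e. age carries no effect).
#' @param baseline_hazard Event hazard per month at linear predictor
#'   0 (default 0.02, median survival near 3 years).
#' @param weibull_shape Weibull shape for event times (default 1 =
#'   exponential).
#' @param censoring_rate Target fraction censored in [0, 1) (default
#'   0.2); independent uniform censoring on (0, c_max) with c_max
#'   solved numerically for the target rate.
#' @param seed Integer seed; same seed gives bit-identical cohorts.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_group1 = 250, n_group2 = 250,
                             n_regulators = 10, targets_per_regulator = 4,
                             rho = 0.8, n_reversed_pairs = 10, delta = 3,
                             betas = c(0.8, -0.5), beta_age = 0,
                             baseline_hazard = 0.02,
                             weibull_shape = 1, censoring_rate = 0.2,
                             seed = 1) {
  cfg <- list(n_group1 = n_group1, n_group2 = n_group2,
              n_regulators = n_regulators,
              targets_per_regulator = targets_per_regulator,
              rho = rho, n_reversed_pairs = n_reversed_pairs, delta = delta,
              betas = betas, beta_age = beta_age,
              baseline_hazard = baseline_hazard,
              weibull_shape = weibull_shape,
              censoring_rate = censoring_rate, seed = seed)
  stopifnot(n_group1 >= 1, n_group2 >= 1, n_regulators >= 1,
            targets_per_regulator >= 1, rho > 0, rho < 1,
            censoring_rate >= 0, censoring_rate < 1,
            baseline_hazard > 0, weibull_shape > 0, delta >= 0)
  if (n_reversed_pairs > n_regulators * targets_per_regulator)
    stop("more planted reversed pairs than regulator-target pairs in the universe")
  if (length(betas) > n_reversed_pairs)
    stop("more prognostic betas than planted reversed pairs")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic cohort with ground truth
#'
#' Each regulator REGk and its targets REGk_Tj are drawn jointly
#' Gaussian, equicorrelated within the block at `rho`. Planted
#' reversed pairs get a grade-dependent mean structure (see
#' [synthetic_config()]) so that the within-sample ordering
#' indicator reverses between groups with probability
#' `pnorm(delta / sqrt(2 * (1 - rho)))` per sample. Survival times
#' are Weibull (default exponential) with hazard
#' `baseline_hazard * exp(sum(beta_i * I_i) + beta_age * (age - 50))`
#' from the true indicators, under independent uniform censoring
#' calibrated to the requested rate. Unrelated noise genes (one per
#' regulator) give the catalog step true negatives.
#'
#' @param config A [synthetic_config()].
#' @return List with `expression` (tibble), `clinical` (tibble:
#'   grade "LGG"/"GBM" plus `age` and `radiotherapy` covariates) and
#'   `truth` (list: `reversed_pairs` — every pair the construction
#'   reverses, i.e. shifted regulators crossed with reversed
#'   targets; `seeded_pairs` — the within-block pairs used to seed
#'   the reversal; `prognostic_pairs` with true beta; per-sample
#'   `linear_predictor`; `pair_universe`; `config`).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_group1 + cf$n_group2
  grp_sign <- rep(c(1, -1), c(cf$n_group1, cf$n_group2))  # +1 = LGG-like
  samples <- sprintf("S%04d", seq_len(n))
  K <- cf$targets_per_regulator

  # reversed pairs round-robin across regulators
  rev_reg <- (seq_len(cf$n_reversed_pairs) - 1L) %% cf$n_regulators + 1L
  rev_tgt <- (seq_len(cf$n_reversed_pairs) - 1L) %/% cf$n_regulators + 1L
  reversed <- sprintf("REG%02d|REG%02d_T%d", rev_reg, rev_reg, rev_tgt)

  rows <- list()
  for (k in seq_len(cf$n_regulators)) {
    f <- stats::rnorm(n)
    block <- sqrt(cf$rho) * matrix(f, nrow = K + 1, ncol = n, byrow = TRUE) +
      sqrt(1 - cf$rho) * matrix(stats::rnorm((K + 1) * n), nrow = K + 1)
    reg <- sprintf("REG%02d", k)
    rownames(block) <- c(reg, sprintf("%s_T%d", reg, seq_len(K)))
    if (k %in% rev_reg) {
      # shared grade effect on the whole block; reversed targets sit
      # delta below it, flipping the regulator-target gap by grade
      block <- block + rep(1.5 * cf$delta * grp_sign, each = K + 1)
      for (tj in rev_tgt[rev_reg == k])
        block[tj + 1, ] <- block[tj + 1, ] - cf$delta * grp_sign
    }
    rows[[k]] <- block
  }
  m <- do.call(rbind, rows)
  noise <- matrix(stats::rnorm(cf$n_regulators * n), ncol = n)
  rownames(noise) <- sprintf("NOISE%02d", seq_len(cf$n_regulators))
  m <- rbind(m, noise) + 8  # positive location typical of log2 units
  colnames(m) <- samples

  age <- round(stats::rnorm(n, mean = ifelse(grp_sign > 0, 43, 58), sd = 12))

  # survival from the true indicators of the prognostic pairs
  betas <- cf$betas
  prognostic <- reversed[seq_along(betas)]
  lp <- cf$beta_age * (age - 50)
  for (i in seq_along(prognostic)) {
    gs <- strsplit(prognostic[i], "|", fixed = TRUE)[[1]]
    lp <- lp + betas[i] * ifelse(m[gs[1], ] >= m[gs[2], ], 1, -1)
  }
  hz <- cf$baseline_hazard * exp(lp)
  t_event <- (-log(stats::runif(n)) / hz)^(1 / cf$weibull_shape)
  cens <- calibrate_censoring(t_event, cf$censoring_rate)
  time <- pmax(pmin(t_event, cens), 1e-6)
  event <- as.integer(t_event <= cens)

  # Ground truth of the construction: every reversed target sits delta
  # below its block's shared grade effect, so its ordering against ANY
  # grade-shifted regulator (not just its own block's) reverses between
  # groups, and the shared grade effect keeps those pairs above the
  # pooled-correlation catalog threshold. The planted reversed set is
  # therefore {shifted regulators} x {reversed targets}.
  shifted_regs <- sprintf("REG%02d", sort(unique(rev_reg)))
  reversed_targets <- sprintf("REG%02d_T%d", rev_reg, rev_tgt)
  reversed_all <- as.vector(outer(shifted_regs, reversed_targets,
                                  function(r, t) paste(r, t, sep = "|")))
  all_targets <- setdiff(rownames(m), sprintf("REG%02d", seq_len(cf$n_regulators)))
  pair_universe <- as.vector(outer(sprintf("REG%02d", seq_len(cf$n_regulators)),
                                   all_targets,
                                   function(r, t) paste(r, t, sep = "|")))

  expression <- dplyr::bind_cols(
    tibble::tibble(gene = rownames(m)),
    tibble::as_tibble(as.data.frame(m, check.names = FALSE)))
  clinical <- tibble::tibble(
    sample_id = samples,
    time_months = time,
    event = event,
    grade = ifelse(grp_sign > 0, "LGG", "GBM"),
    age = age,
    radiotherapy = sample(c("yes", "no"), n, replace = TRUE, prob = c(0.7, 0.3))
  )
  list(expression = validate_expression(expression),
       clinical = validate_clinical(clinical),
       truth = list(reversed_pairs = reversed_all,
                    seeded_pairs = reversed,
                    prognostic_pairs = tibble::tibble(pair = prognostic,
                                                      beta = betas),
                    linear_predictor = stats::setNames(lp, samples),
                    pair_universe = pair_universe,
                    config = cf))
}

# uniform censoring C ~ U(0, c_max); solve c_max so that the realized
# fraction with T > C matches the target rate
calibrate_censoring <- function(t_event, rate) {
  n <- length(t_event)
  if (rate <= 0) return(rep(Inf, n))
  u <- stats::runif(n)
  frac_cens <- function(cmax) mean(t_event > u * cmax)
  lo <- 1e-6; hi <- max(t_event) * 100
  for (it in 1:200) {
    mid <- sqrt(lo * hi)
    if (frac_cens(mid) > rate) lo <- mid else hi <- mid
  }
  u * sqrt(lo * hi)
}

#' Precision/recall of pair recovery against planted truth
#'
#' @param truth Truth list from [generate_cohort()].
#' @param selected_pairs Character vector of selected pair keys, or a
#'   tibble with a `pair` column (e.g. [select_reversed_pairs()]
#'   output).
#' @param signature Optional fitted `pair_signature`; when given, the
#'   absolute error of each fitted coefficient against the true beta
#'   of its planted pair is reported.
#' @return List with `precision`, `recall` (precision is `NA` when
#'   nothing was selected) and, if a signature was supplied,
#'   `coefficient_errors` (tibble pair, true_beta, fitted, abs_error;
#'   `true_beta` 0 for pairs with no planted hazard effect).
#' @export
recovery_report <- function(truth, selected_pairs, signature = NULL) {
  if (is.data.frame(selected_pairs)) selected_pairs <- selected_pairs$pair
  planted <- truth$reversed_pairs
  tp <- length(intersect(selected_pairs, planted))
  out <- list(
    precision = if (length(selected_pairs) == 0) NA_real_
                else tp / length(selected_pairs),
    recall = tp / length(planted)
  )
  if (!is.null(signature)) {
    keys <- paste(signature$entries$regulator, signature$entries$target,
                  sep = "|")
    truth_beta <- stats::setNames(truth$prognostic_pairs$beta,
                                  truth$prognostic_pairs$pair)
    tb <- ifelse(keys %in% names(truth_beta), truth_beta[keys], 0)
    out$coefficient_errors <- tibble::tibble(
      pair = keys,
      true_beta = unname(tb),
      fitted = signature$entries$coefficient,
      abs_error = abs(signature$entries$coefficient - unname(tb))
    )
  }
  out
}
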