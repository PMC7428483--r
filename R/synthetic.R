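#' Simulation configuration for a synthetic learning-fMRI cohort
#'
#' Defines the study conditions emulated by the cohort generator: five task
#' states (rest, EL learning, T&E learning, EL test, T&E test) scanned at
#' TR = 3 s for 200 volumes, a 264-node parcellation with 58 default-mode
#' (DMN), 25 fronto-parietal (FPN) and 181 other nodes, and 43 subjects.
#'
#' Node signals are zero-mean multivariate normal draws whose correlation
#' matrix has block structure: a baseline correlation `rho0` everywhere, plus
#' condition-specific boosts inside the DMN block, inside the FPN block, and
#' on the DMN-x-FPN rectangle. A per-subject effect `d` (SD `tau`) shifts the
#' DMN-x-FPN rectangle by `-d/2` in EL learning and `+d/2` in T&E learning,
#' planting an individual between-network connectivity difference; behavioral
#' scores couple to the same `d` (slope `slope_a`, noise `sigma_b`), planting
#' the brain-behavior correlation the analysis is designed to detect.
#'
#' Default effect sizes are calibration products: they are tuned (see
#' `scripts/calibrate.R`) so that, at the default cohort size, the group
#' contrasts reproduce the qualitative learning/test significance pattern the
#' pipeline targets and the planted brain-behavior Spearman correlation is
#' approximately 0.32.
#'
#' @param n_subjects Cohort size (default 43).
#' @param n_dmn,n_fpn,n_other Node counts per network (defaults 58/25/181).
#' @param n_volumes Volumes per run (default 200, i.e. 10 min at TR 3 s).
#' @param tr_seconds Repetition time in seconds (default 3).
#' @param rho0 Baseline off-block correlation (default 0.1).
#' @param dmn_boost,fpn_boost,between_boost Named numeric vectors of
#'   condition-specific correlation boosts over
#'   `rest, el_learn, te_learn, el_test, te_test`.
#' @param omega SD of the run-level block fluctuation: each simulated run
#'   draws independent zero-mean Gaussian perturbations of the DMN, FPN and
#'   DMN-x-FPN block correlations, emulating the run-to-run state
#'   variability of real recordings (without it, condition contrasts at
#'   realistic cohort sizes would be implausibly noise-free).
#' @param tau SD of the per-subject between-network effect.
#' @param slope_a Slope coupling the subject effect to the latent score
#'   difference (score units per correlation unit).
#' @param sigma_b SD of the behavioral noise on the latent score difference
#'   (score units).
#' @param score_mean,score_sd Mean and SD of the shared subject ability term
#'   on the 0-400 score scale.
#' @param phi AR(1) coefficient of the optional temporal autocorrelation
#'   (default 0: temporally white).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 43L,
                       n_dmn = 58L, n_fpn = 25L, n_other = 181L,
                       n_volumes = 200L, tr_seconds = 3,
                       rho0 = 0.1,
                       dmn_boost = c(rest = 0, el_learn = -0.011, te_learn = 0.05,
                                     el_test = 0, te_test = 0),
                       fpn_boost = c(rest = 0, el_learn = 0.15, te_learn = 0.15,
                                     el_test = 0.12, te_test = 0.12),
                       between_boost = c(rest = 0, el_learn = 0.06, te_learn = 0.06,
                                         el_test = 0, te_test = 0),
                       omega = 0.02,
                       tau = 0.05, slope_a = 569, sigma_b = 64,
                       score_mean = 190, score_sd = 65,
                       phi = 0) {
  conds <- c("rest", "el_learn", "te_learn", "el_test", "te_test")
  for (b in list(dmn_boost, fpn_boost, between_boost))
    if (!all(conds %in% names(b)))
      stop("boost vectors must name all five conditions")
  if (n_subjects < 2) stop("need at least 2 subjects")
  if (n_volumes < 6) stop("need at least 6 volumes")
  if (abs(phi) >= 1) stop("phi must lie in (-1, 1)")
  structure(list(n_subjects = as.integer(n_subjects),
                 n_dmn = as.integer(n_dmn), n_fpn = as.integer(n_fpn),
                 n_other = as.integer(n_other),
                 n_nodes = as.integer(n_dmn + n_fpn + n_other),
                 n_volumes = as.integer(n_volumes), tr_seconds = tr_seconds,
                 rho0 = rho0, dmn_boost = dmn_boost[conds],
                 fpn_boost = fpn_boost[conds], between_boost = between_boost[conds],
                 omega = omega, tau = tau, slope_a = slope_a, sigma_b = sigma_b,
                 score_mean = score_mean, score_sd = score_sd,
                 phi = phi, conditions = conds),
            class = "sim_config")
}

#' Synthetic parcellation matching a simulation configuration
#'
#' Builds a deterministic parcellation table with the configured DMN / FPN /
#' other node counts. Coordinates are synthetic placeholders (a regular
#' 15 mm grid), adequate for format round-trips and spherical extraction
#' tests; they are not anatomical locations.
#'
#' @param config A [sim_config()].
#' @return A [parcellation()].
#' @export
make_parcellation <- function(config) {
  n <- config$n_nodes
  side <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                             z = seq_len(side)))[seq_len(n), , drop = FALSE]
  g <- (g - (side + 1) / 2) * 15
  parcellation(node_id = sprintf("node%03d", seq_len(n)),
               x = g[, 1], y = g[, 2], z = g[, 3],
               network = rep(c("DMN", "FPN", "other"),
                             c(config$n_dmn, config$n_fpn, config$n_other)))
}

#' Block-structured node correlation matrix for one condition
#'
#' Unit-diagonal matrix with `rho0` off-block, `rho0 + dmn_boost[cond]`
#' inside the DMN block, `rho0 + fpn_boost[cond]` inside the FPN block, and
#' `rho0 + between_boost[cond] + between_shift` on DMN-x-FPN cells. If the
#' raw construction is not positive definite it is repaired by flooring
#' eigenvalues at 1e-6 and renormalizing to unit diagonal.
#'
#' @param config A [sim_config()].
#' @param condition One of the five condition labels.
#' @param between_shift Additional shift of the DMN-x-FPN block beyond the
#'   condition boost (carries the subject effect and any run-level
#'   fluctuation; default 0).
#' @param dmn_shift,fpn_shift Additional shifts of the DMN and FPN blocks
#'   (run-level fluctuations; default 0).
#' @param repair If `FALSE`, return the raw construction without the
#'   positive-definite repair.
#' @return A node-by-node correlation matrix.
#' @export
make_covariance <- function(config, condition, between_shift = 0,
                            dmn_shift = 0, fpn_shift = 0, repair = TRUE) {
  stopifnot(inherits(config, "sim_config"), condition %in% config$conditions)
  n <- config$n_nodes
  dmn <- seq_len(config$n_dmn)
  fpn <- config$n_dmn + seq_len(config$n_fpn)
  S <- matrix(config$rho0, n, n)
  S[dmn, dmn] <- config$rho0 + config$dmn_boost[[condition]] + dmn_shift
  S[fpn, fpn] <- config$rho0 + config$fpn_boost[[condition]] + fpn_shift
  bet <- config$rho0 + config$between_boost[[condition]] + between_shift
  S[dmn, fpn] <- bet
  S[fpn, dmn] <- bet
  diag(S) <- 1
  if (any(S >= 1 & row(S) != col(S)) || any(S <= -1))
    stop("block correlations must lie strictly inside (-1, 1)")
  if (repair) S <- .repair_pd(S)
  S
}

.repair_pd <- function(S, floor = 1e-6) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(S)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  S2 <- e$vectors %*% (vals * t(e$vectors))
  S2 <- stats::cov2cor(S2)
  if (inherits(tryCatch(chol(S2), error = function(e) NULL), "NULL"))
    stop("covariance could not be repaired to positive definite")
  S2
}

#' Simulate one subject-condition ROI time series
#'
#' Draws `n_volumes` observations from a zero-mean multivariate normal with
#' the block covariance of [make_covariance()]. With `phi != 0` the draws
#' follow a stationary AR(1) process per node (innovations scaled by
#' `sqrt(1 - phi^2)`), preserving the target contemporaneous covariance.
#'
#' @inheritParams make_covariance
#' @param chol_factor Optional pre-computed upper Cholesky factor of the
#'   covariance (performance path for cohort simulation).
#' @return A [roi_timeseries()].
#' @export
simulate_subject <- function(config, condition, between_shift = 0,
                             chol_factor = NULL) {
  if (is.null(chol_factor))
    chol_factor <- chol(make_covariance(config, condition, between_shift))
  T_ <- config$n_volumes
  n <- config$n_nodes
  Z <- matrix(stats::rnorm(T_ * n), T_, n) %*% chol_factor
  phi <- config$phi
  if (phi != 0) {
    X <- Z
    X[1, ] <- Z[1, ]
    s <- sqrt(1 - phi^2)
    for (t in 2:T_) X[t, ] <- phi * X[t - 1, ] + s * Z[t, ]
    Z <- X
  }
  roi_timeseries(Z, tr_seconds = config$tr_seconds,
                 node_ids = sprintf("node%03d", seq_len(n)))
}

#' Simulate behavioral scores coupled to the subject effects
#'
#' Each subject's latent score difference is `slope_a * d + N(0, sigma_b)`;
#' EL and T&E scores are a shared ability term (mean `score_mean`, SD
#' `score_sd`) minus/plus half the latent difference, rounded to multiples
#' of 10 and clipped to the 0-400 test scale.
#'
#' @param config A [sim_config()].
#' @param subject_effects Numeric vector of per-subject effects `d`.
#' @return Data frame: `subject`, `el_score`, `te_score`.
#' @export
simulate_scores <- function(config, subject_effects) {
  n <- length(subject_effects)
  ability <- stats::rnorm(n, config$score_mean, config$score_sd)
  latent <- config$slope_a * subject_effects + stats::rnorm(n, 0, config$sigma_b)
  snap <- function(v) as.integer(pmin(400, pmax(0, round(v / 10) * 10)))
  data.frame(subject = sprintf("sub%02d", seq_len(n)),
             el_score = snap(ability - latent / 2),
             te_score = snap(ability + latent / 2),
             stringsAsFactors = FALSE)
}

#' Simulate a complete synthetic cohort
#'
#' Draws one subject effect per subject (SD `tau`), reuses it across
#' conditions — entering the DMN-x-FPN block as `-d/2` in EL learning and
#' `+d/2` in T&E learning, 0 elsewhere — draws independent run-level block
#' fluctuations (SD `omega`) for every subject-condition run, simulates the
#' corresponding time series, and generates coupled behavioral scores.
#' Deterministic for a fixed R random seed.
#'
#' @param config A [sim_config()].
#' @param conditions Conditions to simulate (default: all five).
#' @return A list of class `synthetic_cohort`: `ts` (nested list
#'   `ts[[subject]][[condition]]`), `scores`, `parcellation`,
#'   `subject_effects`, `config`.
#' @export
simulate_cohort <- function(config, conditions = config$conditions) {
  stopifnot(inherits(config, "sim_config"), all(conditions %in% config$conditions))
  d <- stats::rnorm(config$n_subjects, 0, config$tau)
  subjects <- sprintf("sub%02d", seq_len(config$n_subjects))
  shift_for <- function(cond, di) switch(cond, el_learn = -di / 2,
                                         te_learn = +di / 2, 0)
  ts <- stats::setNames(vector("list", length(subjects)), subjects)
  for (i in seq_along(subjects)) {
    ts[[i]] <- stats::setNames(vector("list", length(conditions)), conditions)
    for (cond in conditions) {
      eta <- stats::rnorm(3, 0, config$omega)
      S <- make_covariance(config, cond,
                           between_shift = shift_for(cond, d[i]) + eta[3],
                           dmn_shift = eta[1], fpn_shift = eta[2])
      ts[[i]][[cond]] <- simulate_subject(config, cond, chol_factor = chol(S))
    }
  }
  scores <- simulate_scores(config, d)
  structure(list(ts = ts, scores = scores,
                 parcellation = make_parcellation(config),
                 subject_effects = d, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d conditions, %d nodes, %d volumes\n",
              length(x$ts), length(x$ts[[1]]), x$config$n_nodes,
              x$config$n_volumes))
  invisible(x)
}
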