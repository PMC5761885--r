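# Synthetic raters.  Ratings are drawn from exactly the model class the
# analysis assumes -- a cumulative-logistic law with participant random
# intercepts on the latent difficulty scale -- so that the fitting
# module's likelihood is correctly specified by construction and
# parameter recovery is a meaningful test.

#' Simulation parameters for synthetic difficulty ratings
#'
#' The `"exp1"` preset mimics the first published design: 32
#' participants each rating between 60 and 296 of the 296 trials,
#' ordinal ratings 1-10 with a left-skewed marginal distribution, a
#' normally distributed participant intercept, and fixed effects (on the
#' contrast basis of [build_design()]) that reproduce the qualitative
#' ordering of the published condition estimates -- harder with more
#' missing beats, temporal rhythms slightly harder than intensity
#' rhythms, and a positive missing-beats-by-training interaction.
#' Effect magnitudes are free choices of the generator, not estimates
#' from the published data.  Years of musical training are drawn from a
#' two-component mixture: mass near zero for musical novices and a broad
#' 3-25 year range for trained listeners.
#'
#' @param preset `"exp1"` or `"exp2"` (the latter only changes the
#'   number of participants to 25).
#' @param n_participants,ratings_range,beta,theta,sigma_b,
#'   training_novice_prob,training_novice_range,training_trained_range
#'   Overrides of individual preset fields.
#' @return List of class `"simulation_params"`.
#' @export
simulation_params <- function(preset = c("exp1", "exp2"),
                              n_participants = NULL,
                              ratings_range = NULL,
                              beta = NULL, theta = NULL, sigma_b = NULL,
                              training_novice_prob = 0.35,
                              training_novice_range = c(0, 1.5),
                              training_trained_range = c(3, 25)) {
  preset <- match.arg(preset)
  par <- list(
    preset = preset,
    n_participants = if (preset == "exp1") 32L else 25L,
    ratings_range = c(60L, 296L),
    beta = c(mb_simple = 1.1, mb_lin = 0.9, mb_quad = -0.15,
             ob_lin = 0.15, type = 0.35, training = -0.02,
             "mb_simple:training" = 0.04, "mb_lin:training" = 0.05,
             "type:training" = -0.025),
    theta = c(-0.6, 0.3, 1.0, 1.6, 2.2, 2.8, 3.4, 4.1, 5.0),
    sigma_b = 0.9,
    training_novice_prob = training_novice_prob,
    training_novice_range = training_novice_range,
    training_trained_range = training_trained_range
  )
  if (!is.null(n_participants)) par$n_participants <- as.integer(n_participants)
  if (!is.null(ratings_range)) par$ratings_range <- as.integer(ratings_range)
  if (!is.null(beta)) par$beta <- beta
  if (!is.null(theta)) par$theta <- theta
  if (!is.null(sigma_b)) par$sigma_b <- sigma_b
  if (any(diff(par$theta) <= 0)) stop("thresholds must be strictly increasing")
  class(par) <- "simulation_params"
  par
}

#' Draw a panel of synthetic participants
#'
#' @param params A [simulation_params()].
#' @return Data frame `participant_id`, `training_years`.
#' @export
simulate_participants <- function(params) {
  n <- params$n_participants
  novice <- stats::runif(n) < params$training_novice_prob
  tr <- numeric(n)
  tr[novice] <- stats::runif(sum(novice), params$training_novice_range[1L],
                             params$training_novice_range[2L])
  tr[!novice] <- stats::runif(sum(!novice), params$training_trained_range[1L],
                              params$training_trained_range[2L])
  data.frame(participant_id = sprintf("p%02d", seq_len(n)),
             training_years = round(tr, 1))
}

#' Simulate ordinal difficulty ratings for a stimulus set
#'
#' Each participant receives a seeded draw of trials (between the
#' configured minimum and maximum, without replacement) and rates each
#' one: with participant intercept `b_i ~ N(0, sigma_b^2)` and design
#' row `x`, the rating takes category `k` with probability
#' `logistic(theta_k - x'beta - b_i) - logistic(theta_{k-1} - ...)`,
#' the exact cumulative-logistic law (no latent-noise discretisation
#' shortcut).
#'
#' @param params A [simulation_params()].
#' @param stimuli A [build_experiment_stimuli()] result (or any data
#'   frame with `trial_id`, `accent_type`, `missing_beats`, `category`,
#'   `ioi_ms`).
#' @param seed Integer seed (mandatory; the record set is a pure
#'   function of `(params, stimuli, seed)`).
#' @param participants Optional participant table; drawn from `params`
#'   when omitted.
#' @return Data frame of rating records: `participant_id`, `trial_id`,
#'   `accent_type`, `missing_beats`, `off_beat_category`,
#'   `training_years`, `ioi_ms`, `rating`.
#' @export
simulate_ratings <- function(params, stimuli, seed, participants = NULL) {
  stopifnot(inherits(params, "simulation_params"))
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  if (is.null(participants)) participants <- simulate_participants(params)
  n_trials <- nrow(stimuli)
  lo <- min(params$ratings_range[1L], n_trials)
  hi <- min(params$ratings_range[2L], n_trials)
  rows <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    k <- if (lo == hi) lo else (lo:hi)[sample.int(hi - lo + 1L, 1L)]
    idx <- sort(sample.int(n_trials, k))
    rows[[i]] <- data.frame(
      participant_id = participants$participant_id[i],
      trial_id = stimuli$trial_id[idx],
      accent_type = stimuli$accent_type[idx],
      missing_beats = stimuli$missing_beats[idx],
      off_beat_category = stimuli$category[idx],
      training_years = participants$training_years[i],
      ioi_ms = stimuli$ioi_ms[idx],
      stringsAsFactors = FALSE
    )
  }
  rec <- do.call(rbind, rows)
  b <- stats::rnorm(nrow(participants), 0, params$sigma_b)
  names(b) <- participants$participant_id
  rec$rating <- draw_ordinal(rec, params, b[rec$participant_id])
  rownames(rec) <- NULL
  attr(rec, "intercepts") <- b     # true draws, for recovery diagnostics
  rec
}

# Categorical draw from the cumulative-logistic law.  `beta` is matched
# to candidate design columns by name; unnamed effects are an error so
# that typos cannot silently become null effects.
draw_ordinal <- function(records, params, b) {
  eta <- latent_predictor(records, params) + b
  K <- length(params$theta) + 1L
  cum <- vapply(params$theta, function(th) stats::plogis(th - eta),
                numeric(length(eta)))
  cum <- cbind(cum, 1)
  pr <- cum - cbind(0, cum[, -K, drop = FALSE])
  u <- stats::runif(length(eta))
  as.integer(max.col(u <= cum, ties.method = "first"))
}

# x'beta on the contrast basis, for true (simulation) coefficients.
latent_predictor <- function(records, params) {
  design <- build_design_candidates(records)
  beta <- params$beta
  unknown <- setdiff(names(beta), colnames(design))
  if (length(unknown))
    stop("unknown coefficient name(s): ", paste(unknown, collapse = ", "))
  as.vector(design[, names(beta), drop = FALSE] %*% beta)
}

# Full candidate column matrix (no rank reduction), training centred at
# the sample mean as in the fitting path.
build_design_candidates <- function(records) {
  d <- build_design(records, tol = -1)   # tol < 0 keeps every column
  d$X
}

#' Apply the minimum-ratings inclusion filter
#'
#' Removes every record of participants who contributed fewer than
#' `min_count` ratings (participants with exactly `min_count` are
#' kept), mirroring the dropout rule of the published analyses.
#'
#' @param records Rating records.
#' @param min_count Inclusion threshold (default 60).
#' @return Filtered records.
#' @export
apply_inclusion_filter <- function(records, min_count = 60) {
  if (nrow(records) == 0L) return(records)
  n_by <- table(records$participant_id)
  keep <- names(n_by)[n_by >= min_count]
  out <- records[records$participant_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write or read a ratings table
#'
#' Comma-separated text with the documented header
#' `participant_id, trial_id, accent_type, missing_beats,
#' off_beat_category, training_years, ioi_ms, rating`.
#'
#' @param records Rating records.
#' @param path File path.
#' @export
write_ratings <- function(records, path) {
  cols <- c("participant_id", "trial_id", "accent_type", "missing_beats",
            "off_beat_category", "training_years", "ioi_ms", "rating")
  utils::write.csv(records[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
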