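#' Chi-square based eta-squared effect size
#'
#' Friedman's effect-size approximation for likelihood-ratio
#' chi-square statistics: `chi2 / N` for one degree of freedom and
#' `chi2 / (chi2 + N)` for more than one.  Values are returned at full
#' precision; reports round to three decimals.
#'
#' @param chi2 Likelihood-ratio statistic.  A small negative value (a
#'   convergence artifact) is clamped to zero with a warning.
#' @param df Degrees of freedom of the test (>= 1).
#' @param N Number of ratings entering the model.
#' @return Numeric effect size in `[0, 1)`.
#' @examples
#' eta_squared(314.66, 1, 5297)  # 0.0594...
#' eta_squared(256.87, 3, 5297)  # 0.0463...
#' @export
eta_squared <- function(chi2, df, N) {
  stopifnot(df >= 1, N > 0)
  if (any(chi2 < 0)) {
    warning("negative likelihood ratio clamped to 0")
    chi2 <- pmax(chi2, 0)
  }
  ifelse(df == 1, chi2 / N, chi2 / (chi2 + N))
}

#' Likelihood-ratio tests for every model term
#'
#' Refits the model without each term's retained columns (all other
#' columns kept) and reports the likelihood-ratio chi-square, its
#' degrees of freedom (the columns dropped), the p-value and the
#' [eta_squared()] effect size.
#'
#' @param records Rating records, as in [fit_clmm()].
#' @param fit A fitted full model; defaults to fitting one.
#' @param nodes Quadrature nodes for the refits.
#' @param terms Terms to test (default: every term of the design).
#' @return Data frame of class `"clmm_term_tests"` with one row per
#'   term: `term`, `chi2`, `df`, `eta2`, `p`, `converged`.
#' @export
lr_term_tests <- function(records, fit = fit_clmm(records),
                          nodes = fit$nodes, terms = fit$design$terms) {
  design <- fit$design
  out <- data.frame(term = terms, chi2 = NA_real_,
                    df = unname(design$term_df[terms]),
                    eta2 = NA_real_, p = NA_real_, converged = FALSE,
                    stringsAsFactors = FALSE)
  p <- length(fit$coefficients)
  K1 <- length(fit$thresholds)
  for (i in seq_len(nrow(out))) {
    tm <- out$term[i]
    keep <- design$term != tm
    if (out$df[i] == 0L) {           # term fully aliased: nothing to test
      out$chi2[i] <- 0; out$p[i] <- 1; out$eta2[i] <- 0
      out$converged[i] <- TRUE
      next
    }
    red_design <- design
    red_design$X <- design$X[, keep, drop = FALSE]
    red_design$term <- design$term[keep]
    red_design$terms <- setdiff(design$terms, tm)
    red_design$term_df <- design$term_df[red_design$terms]
    start <- list(beta = fit$coefficients[keep],
                  alpha = alpha_from_theta(fit$thresholds),
                  zeta = if (fit$random) log(max(fit$sigma_b, 1e-3)))
    red <- tryCatch(
      fit_clmm(records, red_design, nodes = nodes, random = fit$random,
               start = start, hessian = FALSE),
      warning = function(w) {
        f <- suppressWarnings(fit_clmm(records, red_design, nodes = nodes,
                                       random = fit$random, start = start,
                                       hessian = FALSE))
        f$convergence <- 1L
        f
      })
    out$chi2[i] <- 2 * (fit$logLik - red$logLik)
    out$p[i] <- stats::pchisq(max(out$chi2[i], 0), out$df[i],
                              lower.tail = FALSE)
    out$eta2[i] <- suppressWarnings(eta_squared(out$chi2[i], out$df[i],
                                                fit$N))
    out$converged[i] <- red$convergence == 0L
  }
  class(out) <- c("clmm_term_tests", "data.frame")
  out
}

#' @export
print.clmm_term_tests <- function(x, ...) {
  y <- x
  y$chi2 <- sprintf("%.2f", y$chi2)
  y$eta2 <- sprintf("%.3f", y$eta2)
  y$p <- ifelse(x$p < 0.001, "<0.001", sprintf("%.3f", x$p))
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Wald test and effect size for a single contrast
#'
#' Tests one retained design column (or an arbitrary linear combination
#' of the coefficients): `z = estimate / SE`, a two-sided normal
#' p-value, and the correlation-style effect size `r = z / sqrt(N)`
#' (the convention that reproduces the published pairs of z and r).
#'
#' @param fit A `"clmm_fit"`.
#' @param contrast Column name, or numeric vector over the retained
#'   coefficients.
#' @return List with `estimate`, `se`, `z`, `p`, `r`.
#' @export
contrast_wald <- function(fit, contrast) {
  beta <- fit$coefficients
  if (is.character(contrast)) {
    if (!contrast %in% names(beta))
      stop(sprintf("contrast '%s' is not a retained column %s", contrast,
                   "(it may have been dropped as aliased)"))
    v <- as.numeric(names(beta) == contrast)
  } else {
    stopifnot(length(contrast) == length(beta))
    v <- contrast
  }
  Vb <- fit$vcov[seq_along(beta), seq_along(beta), drop = FALSE]
  est <- sum(v * beta)
  se <- sqrt(drop(t(v) %*% Vb %*% v))
  z <- if (est == 0) 0 else est / se
  list(estimate = est, se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       r = z / sqrt(fit$N))
}

#' Latent-scale condition estimates
#'
#' Linear-predictor values `x' beta` (random effect at zero) for a grid
#' of conditions, with delta-method standard errors.  On this normalised
#' difficulty scale negative values mean "easier to tap to" and positive
#' values "harder".  For report parity with the published figures a
#' two-year split of musical training is supported via the
#' `training_years` argument.
#'
#' @param fit A `"clmm_fit"`.
#' @param conditions Data frame with `missing_beats`,
#'   `off_beat_category`, `accent_type`; defaults to the used conditions
#'   of the Experiment-1 design crossed with both accent types.
#' @param training_years Numeric vector of training levels at which to
#'   evaluate (e.g. `c(1, 10)` for the novice/expert display split).
#' @return Data frame with the condition grid, `training_years`,
#'   `estimate`, `se`.
#' @export
condition_estimates <- function(fit, conditions = NULL,
                                training_years = c(1, 10)) {
  design <- fit$design
  if (is.null(conditions)) {
    cfg <- experiment_config(1)$conditions
    conditions <- expand.grid(i = seq_len(nrow(cfg)),
                              accent_type = c("temporal", "intensity"),
                              stringsAsFactors = FALSE)
    conditions <- data.frame(missing_beats = cfg$missing_beats[conditions$i],
                             off_beat_category = cfg$category[conditions$i],
                             accent_type = conditions$accent_type,
                             stringsAsFactors = FALSE)
  }
  rng <- design$range_training
  grid <- merge(conditions, data.frame(training_years = training_years))
  if (!is.null(rng) &&
      any(grid$training_years < rng[1L] | grid$training_years > rng[2L]))
    warning("training level outside the observed range; extrapolating")
  Xnew <- design_rows(grid, design)
  beta <- fit$coefficients
  Vb <- fit$vcov[seq_along(beta), seq_along(beta), drop = FALSE]
  grid$estimate <- as.vector(Xnew %*% beta)
  grid$se <- sqrt(rowSums((Xnew %*% Vb) * Xnew))
  grid
}

# Rebuild the candidate columns for new data and keep the columns the
# design retained, by name and in order.
design_rows <- function(newdata, design) {
  nd <- newdata
  nd$training_years <- nd$training_years
  blocks <- list(
    missing = mb_codes(nd$missing_beats),
    offbeat = ob_codes(if ("off_beat_category" %in% names(nd))
      nd$off_beat_category else nd$category),
    type = type_codes(nd$accent_type),
    training = cbind(training = nd$training_years - design$center_training)
  )
  cols <- list()
  for (tm in design$terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    m <- blocks[[parts[1L]]]
    if (length(parts) > 1L) for (pp in parts[-1L]) {
      m2 <- blocks[[pp]]
      m <- do.call(cbind, lapply(seq_len(ncol(m2)), function(j) {
        out <- m * m2[, j]
        colnames(out) <- paste(colnames(m), colnames(m2)[j], sep = ":")
        out
      }))
    }
    cols[[tm]] <- m
  }
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(lapply(cols, colnames))
  X[, colnames(design$X), drop = FALSE]
}
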