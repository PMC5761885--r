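toy_records <- function() {
  r <- small_ratings()
  r3 <- r[r$participant_id %in% c("p01", "p02", "p03"), ]
  set.seed(2)
  r3[sort(sample(nrow(r3), 30)), ]
}

test_that("with no predictors and no random effect the thresholds are the empirical cumulative log-odds", {
  r <- small_ratings()
  d0 <- build_design(r, terms = character(0))
  f <- fit_clmm(r, d0, random = FALSE)
  lev <- sort(unique(r$rating))
  emp <- cumsum(table(factor(r$rating, lev))) / nrow(r)
  expect_equal(unname(f$thresholds),
               unname(qlogis(emp[-length(emp)])), tolerance = 1e-6)
})

test_that("the quadrature log-likelihood matches brute-force integration", {
  r3 <- toy_records()
  d3 <- build_design(r3, terms = c("missing", "type"))
  beta <- rep(c(0.8, 0.3, 0.2, -0.1), length.out = ncol(d3$X))
  K <- length(sort(unique(r3$rating)))
  theta <- seq(-1.5, 3, length.out = K - 1)
  ll_bf <- clmm_loglik_bruteforce(r3, d3, beta, theta, 0.8)
  ll_q <- clmm_loglik_quadrature(r3, d3, beta, theta, 0.8, nodes = 15)
  expect_equal(ll_q, ll_bf, tolerance = 1e-7)   # 6+ significant digits
})

test_that("the analytic gradient matches central differences", {
  r <- small_ratings()
  d <- build_design(r, terms = c("missing", "type", "training"))
  y <- match(r$rating, sort(unique(r$rating)))
  K <- length(unique(y))
  eng <- beatgrid:::clmm_engine(d$X, y, K,
                                as.integer(factor(r$participant_id)),
                                nodes = 9)
  par <- c(rep(0.1, ncol(d$X)),
           beatgrid:::alpha_from_theta(seq(-1, 3, length.out = K - 1)),
           log(0.8))
  g_a <- eng$gr(par)
  g_n <- vapply(seq_along(par), function(i) {
    e <- numeric(length(par)); e[i] <- 1e-6
    (eng$fn(par + e) - eng$fn(par - e)) / 2e-6
  }, numeric(1))
  expect_equal(g_a, g_n, tolerance = 1e-5)
})

test_that("the quadrature is converged by 15 nodes", {
  r <- small_ratings()
  d <- build_design(r, terms = c("missing", "type"))
  beta <- rep(0.3, ncol(d$X))
  K <- length(sort(unique(r$rating)))
  theta <- seq(-1, 4, length.out = K - 1)
  l15 <- clmm_loglik_quadrature(r, d, beta, theta, 0.9, nodes = 15)
  l25 <- clmm_loglik_quadrature(r, d, beta, theta, 0.9, nodes = 25)
  expect_lt(abs(l15 - l25), 1e-4)
})

test_that("as sigma_b vanishes the mixed fit approaches the fixed-effects fit", {
  pars <- simulation_params("exp1", n_participants = 10,
                            ratings_range = c(60, 60),
                            beta = c(mb_simple = 0.8, type = 0.3),
                            sigma_b = 0)
  r <- simulate_ratings(pars, stimuli1(), seed = 88)
  d <- build_design(r, terms = c("missing", "type"))
  fx <- fit_clmm(r, d, random = FALSE)
  mx <- fit_clmm(r, d, nodes = 9)
  expect_lt(mx$sigma_b, 0.15)
  expect_equal(mx$coefficients, fx$coefficients, tolerance = 0.02)
  expect_equal(mx$thresholds, fx$thresholds, tolerance = 0.05)
})

test_that("category probabilities sum to one at arbitrary parameters", {
  theta <- c(-1, 0, 0.5, 1, 1.4, 2, 2.5, 3, 4)
  eta <- seq(-3, 3, length.out = 11)
  cum <- cbind(plogis(outer(-eta, theta, `+`)), 1)
  pr <- cum - cbind(0, cum[, -10])
  expect_equal(rowSums(pr), rep(1, 11))
  expect_true(all(pr >= 0))
})

test_that("the marginal likelihood ignores participant labels and row order", {
  r <- small_ratings()
  d <- build_design(r, terms = c("missing", "type"))
  beta <- rep(0.2, ncol(d$X))
  K <- length(sort(unique(r$rating)))
  theta <- seq(-1, 4, length.out = K - 1)
  base <- clmm_loglik_quadrature(r, d, beta, theta, 0.8)
  perm <- sample(nrow(r))
  r2 <- r[perm, ]
  d2 <- d; d2$X <- d$X[perm, , drop = FALSE]
  expect_equal(clmm_loglik_quadrature(r2, d2, beta, theta, 0.8), base,
               tolerance = 1e-10)
  ids <- unique(r$participant_id)
  relabel <- stats::setNames(paste0("z", rev(seq_along(ids))), ids)
  r3 <- r
  r3$participant_id <- unname(relabel[r$participant_id])
  expect_equal(clmm_loglik_quadrature(r3, d, beta, theta, 0.8), base,
               tolerance = 1e-10)
})

test_that("parameters are recovered from data simulated under the model", {
  truth <- c(mb_simple = 1.0, mb_lin = 0.8, type = 0.4)
  pars <- simulation_params("exp1", n_participants = 25,
                            ratings_range = c(120, 120), beta = truth,
                            sigma_b = 0.8)
  r <- simulate_ratings(pars, stimuli1(), seed = 404)
  d <- build_design(r, terms = c("missing", "type"))
  f <- fit_clmm(r, d, nodes = 7)
  expect_equal(f$convergence, 0L)
  se <- sqrt(diag(f$vcov))[seq_along(f$coefficients)]
  names(se) <- names(f$coefficients)
  for (nm in names(truth)) {
    expect_lt(abs(f$coefficients[[nm]] - truth[[nm]]), 3 * se[[nm]])
  }
  expect_lt(abs(f$sigma_b - 0.8), 0.35)
})

test_that("unobserved categories are collapsed and mapped back", {
  r <- small_ratings()
  r$rating[r$rating >= 9] <- 8L    # empty the top two categories
  d <- build_design(r, terms = "type")
  f <- fit_clmm(r, d, nodes = 5)
  expect_length(f$thresholds, 7L)
  expect_equal(names(f$thresholds),
               c("1|2", "2|3", "3|4", "4|5", "5|6", "6|7", "7|8"))
})
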