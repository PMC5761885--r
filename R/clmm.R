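# Cumulative-link mixed model for ordinal difficulty ratings.
#
# Model: P(Y_ij <= k | b_i) = logistic(theta_k - x_ij' beta - b_i),
# b_i ~ N(0, sigma_b^2), ratings on an ordinal 1..K scale.  The marginal
# likelihood integrates the participant intercept out by adaptive
# Gauss-Hermite quadrature centred at the conditional mode; one node
# recovers the Laplace approximation.  Thresholds are parameterised as
# (theta_1, log successive increments) so that monotonicity is
# unconstrained, and the random-effect spread as log sigma.
#
# The analytic gradient treats the adaptive centring (mode and scale) as
# fixed; for adaptive quadrature the neglected terms cancel to
# quadrature accuracy (they integrate a total derivative), so gradient
# and objective agree at the same order as the quadrature itself.  With
# a single node (Laplace) the cancellation is not available and the
# gradient is only approximate; three or more nodes are recommended.

# Gauss-Hermite nodes and weights for weight function exp(-x^2), by
# Golub-Welsch on the Jacobi matrix of the Hermite recurrence.
gauss_hermite <- function(n) {
  stopifnot(n >= 1)
  if (n == 1L) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(n - 1L) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- off
  J[cbind(seq_len(n - 1L) + 1L, seq_len(n - 1L))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord],
       weights = sqrt(pi) * e$vectors[1L, ord]^2)
}

# Stable logistic interval probability P(u0 < L <= u1), L ~ logistic.
interval_prob <- function(u1, u0) {
  flip <- (u1 + u0) > 0
  pr <- stats::plogis(u1) - stats::plogis(u0)
  pr[flip] <- stats::plogis(u0[flip], lower.tail = FALSE) -
    stats::plogis(u1[flip], lower.tail = FALSE)
  pmax(pr, 1e-300)
}

theta_from_alpha <- function(alpha) cumsum(c(alpha[1L], exp(alpha[-1L])))

alpha_from_theta <- function(theta) {
  d <- diff(theta)
  c(theta[1L], log(pmax(d, 1e-6)))
}

# Evaluation engine shared by objective and gradient.  Returns a closure
# environment with fn/gr on the packed parameter (beta, alpha[, zeta]).
# All per-observation work is done on n x nodes matrices so that each
# evaluation costs a handful of vectorised sweeps.
clmm_engine <- function(X, y, K, group, nodes = 9, random = TRUE) {
  n <- length(y)
  p <- ncol(X)
  G <- if (random) max(group) else 0L
  gh <- gauss_hermite(nodes)
  bhat <- numeric(G)                       # warm-started mode per group
  cache_key <- NULL; cache_val <- NULL; cache_grad <- NULL
  yu <- y                                   # index of upper threshold
  # stable interval probability pieces for a matrix (or vector) of
  # deviations; returns log-probability plus the densities needed by
  # the gradient
  pieces <- function(u1, u0) {
    Q1 <- stats::plogis(u1); S1 <- stats::plogis(u1, lower.tail = FALSE)
    Q0 <- stats::plogis(u0); S0 <- stats::plogis(u0, lower.tail = FALSE)
    pr <- Q1 - Q0
    flip <- (u1 + u0) > 0
    pr[flip] <- (S0 - S1)[flip]
    pr <- pmax(pr, 1e-300)
    list(pr = pr, lp = log(pr), f1 = Q1 * S1, f0 = Q0 * S0,
         d1 = S1 - Q1, d0 = S0 - Q0)      # d = 1 - 2F
  }
  evaluate <- function(par) {
    beta <- par[seq_len(p)]
    alpha <- par[p + seq_len(K - 1L)]
    theta <- theta_from_alpha(alpha)
    eta <- as.vector(X %*% beta)
    upper <- c(theta, Inf)[yu] - eta
    lower <- c(-Inf, theta)[yu] - eta
    if (!random) {
      pc <- pieces(upper, lower)
      val <- sum(pc$lp)
      wc <- (pc$f0 - pc$f1) / pc$pr
      T1 <- rowsum_vec(pc$f1 / pc$pr, yu, K)
      T0 <- rowsum_vec(pc$f0 / pc$pr, yu, K)
      gth <- T1[seq_len(K - 1L)] - T0[2L:K]
      grad <- c(crossprod(X, wc), chain_alpha(gth, alpha))
      return(list(value = val, grad = grad))
    }
    zeta <- par[p + K]
    sigma <- exp(zeta)
    s2 <- sigma^2
    # --- conditional modes by damped Newton ---------------------------
    lp_sum <- function(bv) {               # sum log p by group, at bv
      pc <- pieces(upper - bv[group], lower - bv[group])
      rowsum_vec(pc$lp, group, G)
    }
    b <- bhat
    hof <- function(bv, lps) lps - log(sigma) - bv^2 / (2 * s2)
    hcur <- hof(b, lp_sum(b))
    for (it in seq_len(60L)) {
      pc <- pieces(upper - b[group], lower - b[group])
      cc <- (pc$f0 - pc$f1) / pc$pr
      g1 <- rowsum_vec(cc, group, G) - b / s2
      if (max(abs(g1)) < 1e-9) break
      curv <- (pc$f1 * pc$d1 - pc$f0 * pc$d0) / pc$pr - cc^2
      h2 <- pmin(rowsum_vec(curv, group, G) - 1 / s2, -1e-10)
      step <- g1 / h2
      step <- sign(step) * pmin(abs(step), 5 + 5 * sigma)
      repeat {
        bn <- b - step
        hn <- hof(bn, lp_sum(bn))
        if (all(hn >= hcur - 1e-8) || max(abs(step)) < 1e-12) break
        bad <- hn < hcur - 1e-8
        step[bad] <- step[bad] / 2
      }
      b <- bn; hcur <- hn
    }
    bhat <<- b
    pc <- pieces(upper - b[group], lower - b[group])
    cc <- (pc$f0 - pc$f1) / pc$pr
    curv <- (pc$f1 * pc$d1 - pc$f0 * pc$d0) / pc$pr - cc^2
    h2 <- pmin(rowsum_vec(curv, group, G) - 1 / s2, -1e-10)
    s_ad <- 1 / sqrt(-h2)
    # --- adaptive quadrature, all nodes at once ------------------------
    Kq <- length(gh$nodes)
    B <- b + (sqrt(2) * s_ad) %o% gh$nodes          # G x Kq
    Bo <- B[group, , drop = FALSE]                   # n x Kq
    pcq <- pieces(upper - Bo, lower - Bo)
    LPg <- rowsum(pcq$lp, group)                     # G x Kq
    Hmat <- LPg - 0.5 * log(2 * pi) - log(sigma) - B^2 / (2 * s2) +
      rep(log(gh$weights) + gh$nodes^2, each = G)
    hmax <- apply(Hmat, 1L, max)
    lse <- hmax + log(rowSums(exp(Hmat - hmax)))
    val <- sum(log(sqrt(2) * s_ad) + lse)
    # --- gradient -------------------------------------------------------
    omega <- exp(Hmat - lse)               # G x Kq posterior node weights
    wobs <- omega[group, , drop = FALSE]
    wc <- rowSums(wobs * (pcq$f0 - pcq$f1) / pcq$pr)
    t1 <- rowSums(wobs * pcq$f1 / pcq$pr)
    t0 <- rowSums(wobs * pcq$f0 / pcq$pr)
    gzeta <- sum(omega * (B^2 / s2 - 1))
    T1 <- rowsum_vec(t1, yu, K)
    T0 <- rowsum_vec(t0, yu, K)
    gth <- T1[seq_len(K - 1L)] - T0[2L:K]
    grad <- c(crossprod(X, wc), chain_alpha(gth, alpha), gzeta)
    list(value = val, grad = grad)
  }
  both <- function(par) {
    if (!identical(par, cache_key)) {
      res <- evaluate(par)
      cache_key <<- par
      cache_val <<- res$value
      cache_grad <<- res$grad
    }
    list(value = cache_val, grad = cache_grad)
  }
  list(
    fn = function(par) -both(par)$value,
    gr = function(par) -both(par)$grad,
    loglik = function(par) both(par)$value,
    reset = function() bhat <<- numeric(G)
  )
}

rowsum_vec <- function(x, index, nbin) {
  out <- numeric(nbin)
  r <- rowsum(x, index)
  out[as.integer(rownames(r))] <- r[, 1L]
  out
}

# d loglik / d alpha from d loglik / d theta under the increment
# parameterisation theta = cumsum(alpha1, exp(alpha[-1])).
chain_alpha <- function(gth, alpha) {
  revcum <- rev(cumsum(rev(gth)))
  c(revcum[1L], exp(alpha[-1L]) * revcum[-1L])
}

#' Fit a cumulative-link (mixed) model to ordinal ratings
#'
#' Maximum-likelihood fit of a proportional-odds model with logistic
#' link and an optional participant random intercept integrated out by
#' adaptive Gauss-Hermite quadrature.  Written for the difficulty-rating
#' design of this package but usable with any design matrix.
#'
#' Ratings whose category is never observed are collapsed out of the
#' threshold set during fitting and the retained thresholds are mapped
#' back to the full 1-10 scale in the output.
#'
#' @param records Data frame with `rating` (integers 1..10),
#'   `participant_id`, and the factor columns consumed by
#'   [build_design()].
#' @param design A `"clmm_design"`; defaults to the full-interaction
#'   design built from `records`.
#' @param nodes Number of quadrature nodes (1 = Laplace; 3 or more
#'   recommended, default 9).
#' @param random Include the participant random intercept?
#' @param start Optional named list with `beta`, `alpha`, `zeta`.
#' @param hessian Compute the observed information (needed for standard
#'   errors)?  Skipping it roughly halves the cost of a fit whose only
#'   use is a likelihood comparison.
#' @param control Passed to [stats::nlminb()].
#' @return Object of class `"clmm_fit"`: coefficients, thresholds,
#'   `sigma_b`, `logLik`, `vcov`, `N`, convergence diagnostics.
#' @export
fit_clmm <- function(records, design = build_design(records), nodes = 9,
                     random = TRUE, start = NULL, hessian = TRUE,
                     control = list(rel.tol = 1e-11, iter.max = 1000,
                                    eval.max = 2000)) {
  X <- design$X
  stopifnot(nrow(X) == nrow(records))
  rating <- as.integer(records$rating)
  if (any(rating < 1L | rating > 10L)) stop("ratings must be 1..10")
  lev <- sort(unique(rating))
  if (length(lev) < 2L) stop("need at least two observed rating categories")
  y <- match(rating, lev)
  K <- length(lev)
  if (random) {
    pid <- factor(records$participant_id)
    if (nlevels(pid) < 2L) stop("need at least two participants")
    group <- as.integer(pid)
  } else group <- integer(length(y))
  eng <- clmm_engine(X, y, K, group, nodes = nodes, random = random)
  p <- ncol(X)
  if (is.null(start)) {
    cum <- cumsum(tabulate(y, K) / length(y))[seq_len(K - 1L)]
    cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
    start <- list(beta = numeric(p),
                  alpha = alpha_from_theta(stats::qlogis(cum)),
                  zeta = log(0.7))
  }
  par0 <- c(start$beta, start$alpha, if (random) start$zeta)
  opt <- stats::nlminb(par0, eng$fn, eng$gr, control = control)
  tries <- 0L
  while (opt$convergence != 0L && tries < 3L) {
    tries <- tries + 1L
    eng$reset()
    jit <- par0 * (1 + 0.05 * tries) + 0.01 * tries
    cand <- stats::nlminb(jit, eng$fn, eng$gr, control = control)
    if (cand$objective < opt$objective || cand$convergence == 0L)
      opt <- cand
  }
  par <- opt$par
  gnorm <- max(abs(eng$gr(par)))
  V <- NULL
  if (hessian) {
    H <- stats::optimHess(par, eng$fn, eng$gr)
    V <- tryCatch(solve(H), error = function(e) {
      warning("information matrix is singular; using pseudo-inverse")
      ev <- eigen(H, symmetric = TRUE)
      pos <- ev$values > max(ev$values) * 1e-12
      ev$vectors[, pos] %*% (t(ev$vectors[, pos]) / ev$values[pos])
    })
  }
  beta <- par[seq_len(p)]
  names(beta) <- colnames(X)
  alpha <- par[p + seq_len(K - 1L)]
  theta <- theta_from_alpha(alpha)
  names(theta) <- paste(lev[-K], lev[-1L], sep = "|")
  theta_se <- NULL
  if (!is.null(V)) {
    J <- matrix(0, K - 1L, K - 1L)
    J[, 1L] <- 1
    if (K > 2L) for (l in 2L:(K - 1L)) J[l:(K - 1L), l] <- exp(alpha[l])
    Va <- V[p + seq_len(K - 1L), p + seq_len(K - 1L), drop = FALSE]
    theta_se <- stats::setNames(sqrt(pmax(diag(J %*% Va %*% t(J)), 0)),
                                names(theta))
  }
  sigma_b <- if (random) exp(par[p + K]) else 0
  fit <- list(
    coefficients = beta,
    thresholds = theta,
    threshold_se = theta_se,
    sigma_b = sigma_b,
    logLik = -opt$objective,
    vcov = V,
    par = par,
    N = length(y),
    levels = lev,
    nodes = nodes,
    random = random,
    design = design,
    convergence = opt$convergence,
    message = opt$message,
    gradient_norm = gnorm,
    restarts = tries
  )
  class(fit) <- "clmm_fit"
  if (opt$convergence != 0L)
    warning(sprintf("clmm did not converge (%s); gradient norm %.2e",
                    opt$message, gnorm))
  fit
}

#' @export
print.clmm_fit <- function(x, ...) {
  cat(sprintf("cumulative-link %s, logistic link, %d ratings\n",
              if (x$random) "mixed model (adaptive GHQ)" else "model",
              x$N))
  cat(sprintf("log-likelihood %.4f%s\n", x$logLik,
              if (x$random) sprintf(", sigma_b = %.4f", x$sigma_b) else ""))
  if (length(x$coefficients)) {
    cat("coefficients:\n")
    print(round(x$coefficients, 4))
  }
  cat("thresholds:\n")
  print(round(x$thresholds, 4))
  invisible(x)
}

#' @export
logLik.clmm_fit <- function(object, ...) {
  structure(object$logLik,
            df = length(object$par), class = "logLik")
}

#' @export
vcov.clmm_fit <- function(object, ...) object$vcov

#' Marginal log-likelihood by brute-force numerical integration
#'
#' Reference implementation used to validate the quadrature: integrates
#' the random intercept on a dense trapezoid grid.  Exact to the grid
#' resolution, and deliberately independent of the fitting code path.
#'
#' @param records,design As in [fit_clmm()].
#' @param beta,theta,sigma_b Parameter values at which to evaluate.
#' @param grid_width Half-width of the integration grid in units of
#'   `sigma_b`.
#' @param grid_n Number of grid points.
#' @return The marginal log-likelihood.
#' @export
clmm_loglik_bruteforce <- function(records, design, beta, theta, sigma_b,
                                   grid_width = 12, grid_n = 20001) {
  X <- design$X
  rating <- as.integer(records$rating)
  lev <- sort(unique(rating))
  y <- match(rating, lev)
  K <- length(lev)
  eta <- as.vector(X %*% beta)
  upper <- c(theta, Inf)[y]
  lower <- c(-Inf, theta)[y]
  bgrid <- seq(-grid_width * sigma_b, grid_width * sigma_b,
               length.out = grid_n)
  dz <- bgrid[2L] - bgrid[1L]
  total <- 0
  for (g in unique(records$participant_id)) {
    idx <- records$participant_id == g
    lp <- vapply(bgrid, function(b) {
      sum(log(interval_prob(upper[idx] - eta[idx] - b,
                            lower[idx] - eta[idx] - b)))
    }, numeric(1))
    lw <- lp + stats::dnorm(bgrid, 0, sigma_b, log = TRUE)
    m <- max(lw)
    integrand <- exp(lw - m)
    total <- total + m +
      log(dz * (sum(integrand) - 0.5 * (integrand[1L] +
                                          integrand[grid_n])))
  }
  total
}

#' Marginal log-likelihood at given parameters via the fitting engine
#'
#' Evaluates the adaptive-quadrature log-likelihood used by
#' [fit_clmm()] at arbitrary parameter values, without optimising.
#'
#' @inheritParams clmm_loglik_bruteforce
#' @param nodes Quadrature nodes.
#' @export
clmm_loglik_quadrature <- function(records, design, beta, theta, sigma_b,
                                   nodes = 9) {
  X <- design$X
  rating <- as.integer(records$rating)
  lev <- sort(unique(rating))
  y <- match(rating, lev)
  K <- length(lev)
  pid <- factor(records$participant_id)
  eng <- clmm_engine(X, y, K, as.integer(pid), nodes = nodes,
                     random = TRUE)
  eng$loglik(c(beta, alpha_from_theta(theta), log(sigma_b)))
}
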