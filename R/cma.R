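# Covariance Matrix Adaptation Evolution Strategy (CMA-ES), standard
# (mu/mu_w, lambda) formulation with cumulative step-size adaptation and
# rank-one plus rank-mu covariance updates.  The search runs in box-
# normalized coordinates ([0, 1] per dimension); out-of-box samples are
# redrawn a few times and finally clamped with a quadratic penalty, which
# keeps the covariance update unbiased near the bounds.

#' CMA-ES maximization over a box
#'
#' @param objective Function mapping a parameter vector (original units) to
#'   a scalar quality; larger is better.  Non-finite values are treated as
#'   the worst sample in the population.
#' @param lower,upper Box bounds (equal-length numeric vectors).
#' @param x0 Initial mean in original units (default: box center).
#' @param sigma0 Initial step size as a fraction of the box width.
#' @param popsize Samples per iteration (lambda).
#' @param maxiter Iteration budget.
#' @param seed RNG seed; fixed seeds give bit-identical runs.
#' @param workers Parallel evaluation processes (forked); results are
#'   reduced in sample order so the run is identical to a serial one.
#' @param tol_x Stop when the step size times the largest covariance
#'   eigenvalue drops below this fraction of the box width.
#' @param archive Keep every sample and its quality.
#' @return A `psw_optrun`: `best_par`, `best_value`, per-iteration
#'   `history` (best/mean/best-so-far quality, sigma), `evaluations`,
#'   `seed`, and optionally `archive`.
#' @export
cma_optimize <- function(objective, lower, upper, x0 = NULL, sigma0 = 0.3,
                         popsize = 31, maxiter = 70, seed = 1, workers = 1,
                         tol_x = 1e-12, archive = FALSE) {
  stopifnot(length(lower) == length(upper), all(upper > lower), popsize >= 4)
  n <- length(lower)
  width <- upper - lower
  to_real <- function(z) lower + pmin(pmax(z, 0), 1) * width
  set.seed(seed)
  m <- if (is.null(x0)) rep(0.5, n) else (x0 - lower) / width
  sigma <- sigma0
  lambda <- as.integer(popsize)
  mu <- floor(lambda / 2)
  wts <- log(mu + 0.5) - log(seq_len(mu))
  wts <- wts / sum(wts)
  mueff <- 1 / sum(wts^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))
  pc <- ps <- numeric(n)
  C <- diag(n)
  eig <- list(values = rep(1, n), vectors = diag(n))
  invsqrtC <- diag(n)
  best_value <- -Inf
  best_par <- to_real(m)
  hist <- data.frame(iter = integer(0), best = numeric(0),
                     mean = numeric(0), best_so_far = numeric(0),
                     sigma = numeric(0))
  arch <- if (archive) list() else NULL
  evals <- 0L
  n_nonfinite <- 0L
  eval_all <- function(X) {
    xs <- lapply(seq_len(ncol(X)), function(i) X[, i])
    vals <- if (workers > 1) {
      parallel::mclapply(xs, objective, mc.cores = workers,
                         mc.preschedule = TRUE)
    } else {
      lapply(xs, objective)
    }
    vapply(vals, function(v) {
      v <- suppressWarnings(as.numeric(v)[1])
      if (!is.finite(v)) NA_real_ else v
    }, 0)
  }
  for (iter in seq_len(maxiter)) {
    BD <- eig$vectors %*% diag(sqrt(pmax(eig$values, 1e-20)), n)
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- BD %*% Z
    Xn <- m + sigma * Y
    pen <- numeric(lambda)
    for (i in seq_len(lambda)) {
      tries <- 0
      while ((any(Xn[, i] < 0) || any(Xn[, i] > 1)) && tries < 10) {
        z <- rnorm(n)
        Y[, i] <- BD %*% z
        Xn[, i] <- m + sigma * Y[, i]
        tries <- tries + 1
      }
      if (any(Xn[, i] < 0) || any(Xn[, i] > 1)) {
        clamped <- pmin(pmax(Xn[, i], 0), 1)
        pen[i] <- sum(((Xn[, i] - clamped) / sigma)^2)
        Y[, i] <- (clamped - m) / sigma
        Xn[, i] <- clamped
      }
    }
    X <- apply(Xn, 2, to_real)
    q <- eval_all(X)
    nbad <- sum(is.na(q))
    if (nbad == lambda)
      stop("all ", lambda, " samples failed in iteration ", iter)
    if (nbad > 0) {
      n_nonfinite <- n_nonfinite + nbad
      q[is.na(q)] <- min(q, na.rm = TRUE) - 1
    }
    evals <- evals + lambda
    f <- -(q - pen)                      # minimize penalized negative quality
    ord <- order(f)
    if (q[ord[1]] > best_value) {
      best_value <- q[ord[1]]
      best_par <- X[, ord[1]]
    }
    if (archive) arch[[iter]] <- list(par = X, quality = q)
    ysel <- Y[, ord[seq_len(mu)], drop = FALSE]
    ybar <- as.vector(ysel %*% wts)
    m <- m + sigma * ybar
    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * as.vector(invsqrtC %*% ybar)
    hsig <- as.numeric(
      sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * iter)) / chiN < 1.4 + 2 / (n + 1))
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ybar
    C <- (1 - c1 - cmu) * C +
      c1 * (outer(pc, pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * ysel %*% (wts * t(ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))
    C <- (C + t(C)) / 2
    eig <- eigen(C, symmetric = TRUE)
    eig$values <- pmax(eig$values, 1e-20)
    invsqrtC <- eig$vectors %*% diag(1 / sqrt(eig$values), n) %*% t(eig$vectors)
    hist <- rbind(hist, data.frame(
      iter = iter, best = max(q), mean = mean(q), best_so_far = best_value,
      sigma = sigma))
    if (sigma * sqrt(max(eig$values)) < tol_x) break
  }
  structure(list(best_par = best_par, best_value = best_value,
                 history = hist, evaluations = evals, seed = seed,
                 popsize = lambda, n_nonfinite = n_nonfinite,
                 archive = arch),
            class = "psw_optrun")
}

#' @export
print.psw_optrun <- function(x, ...) {
  cat(sprintf(
    "CMA-ES run: %d evaluations (%d x %d), best quality %.5g (seed %d)\n",
    x$evaluations, x$popsize, nrow(x$history), x$best_value, x$seed))
  invisible(x)
}
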