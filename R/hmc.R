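## Adaptive Hamiltonian Monte Carlo and convergence diagnostics. Leapfrog
## integration with a diagonal mass matrix; dual-averaging step-size
## adaptation toward a target acceptance rate, Stan-style expanding metric
## windows during warmup, and a jittered trajectory-length target. Draws
## are reproducible given the seed. The hierarchical stillbirth model is
## sampled by the blocked sampler in gibbs.R (which reuses the leapfrog
## integrator here); this generic sampler serves free-form targets.

#' MCMC options
#'
#' @param chains number of chains (>= 2 for diagnostics).
#' @param warmup warmup iterations per chain (discarded).
#' @param draws retained iterations per chain.
#' @param target_accept dual-averaging target acceptance probability.
#' @param traj_length target leapfrog trajectory length; the per-iteration
#'   step count is `traj_length / step_size`, jittered by +/-50% and capped
#'   at `max_leapfrog`.
#' @param max_leapfrog cap on leapfrog steps per iteration.
#' @param adapt_metric estimate a diagonal metric during warmup; disable
#'   when the target is already preconditioned to unit scale.
#' @param init_step initial leapfrog step size.
#' @param init_jitter sd of the random initialisation jitter.
#' @param max_divergence_frac warn when the post-warmup divergent fraction
#'   exceeds this.
#' @return list of options.
#' @export
mcmc_options <- function(chains = 4, warmup = 1000, draws = 1000,
                         target_accept = 0.8, traj_length = 1.5,
                         max_leapfrog = 128, adapt_metric = TRUE,
                         init_step = 0.1, init_jitter = 0.1,
                         max_divergence_frac = 0.05) {
  as.list(environment())
}

## Stan-style warmup schedule: an initial step-size-only phase, expanding
## mass-estimation windows (each ending in a metric update and a dual
## averaging restart), and a final step-size-only phase.
warmup_windows <- function(warmup) {
  if (warmup < 60) return(list(fast1 = warmup, ends = integer(0), final = 0L))
  fast1 <- min(75L, max(10L, round(0.15 * warmup)))
  final <- min(50L, max(10L, round(0.10 * warmup)))
  slow <- warmup - fast1 - final
  ends <- integer(0); size <- 25L; at <- fast1
  while (slow >= size) {
    at <- at + size; slow <- slow - size
    ends <- c(ends, at); size <- size * 2L
  }
  if (length(ends)) ends[length(ends)] <- ends[length(ends)] + slow
  else { fast1 <- fast1 + slow }
  list(fast1 = fast1, ends = ends, final = final)
}

leapfrog <- function(lp_grad, theta, p, eps, inv_mass, n_steps, cache) {
  g <- cache$grad
  for (s in seq_len(n_steps)) {
    p <- p + 0.5 * eps * g
    theta <- theta + eps * (inv_mass * p)
    cache <- lp_grad(theta)
    if (!all(is.finite(cache$grad)) || !is.finite(cache$lp))
      return(list(theta = theta, p = p, cache = cache, ok = FALSE))
    g <- cache$grad
    p <- p + 0.5 * eps * g
  }
  list(theta = theta, p = p, cache = cache, ok = TRUE)
}

hmc_chain <- function(lp_grad, theta0, warmup, draws, control, seed,
                      inv_mass0 = NULL) {
  set.seed(seed)
  d <- length(theta0)
  inv_mass <- if (is.null(inv_mass0)) rep(1, d) else inv_mass0
  theta <- theta0
  cache <- lp_grad(theta)
  if (!is.finite(cache$lp)) stop("failed to initialise: non-finite log posterior",
                                 call. = FALSE)
  ## dual averaging state (Hoffman & Gelman 2014 defaults)
  eps <- control$init_step
  mu_da <- log(10 * eps); log_eps_bar <- log(eps); h_bar <- 0; m_da <- 0
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75
  da_restart <- function(eps) {
    mu_da <<- log(10 * eps); log_eps_bar <<- log(eps); h_bar <<- 0; m_da <<- 0
  }

  win <- warmup_windows(warmup)
  window_ends <- win$ends
  total <- warmup + draws
  out <- matrix(NA_real_, draws, d)
  lp_out <- numeric(draws)
  accept <- numeric(total)
  n_div <- 0L
  buf <- NULL

  for (it in seq_len(total)) {
    p0 <- stats::rnorm(d) / sqrt(inv_mass)
    n_steps <- max(1L, min(control$max_leapfrog,
                           round(stats::runif(1, 0.5, 1.5) *
                                   control$traj_length / eps)))
    h0 <- cache$lp - 0.5 * sum(inv_mass * p0^2)
    prop <- leapfrog(lp_grad, theta, p0, eps, inv_mass, n_steps, cache)
    if (prop$ok) {
      h1 <- prop$cache$lp - 0.5 * sum(inv_mass * prop$p^2)
      a <- min(1, exp(h1 - h0))
      if (!is.finite(a)) a <- 0
      divergent <- (h0 - h1) > 1000
    } else {
      a <- 0; divergent <- TRUE
    }
    if (divergent && it > warmup) n_div <- n_div + 1L
    if (stats::runif(1) < a) { theta <- prop$theta; cache <- prop$cache }
    accept[it] <- a

    if (it <= warmup) {
      m_da <- m_da + 1
      h_bar <- (1 - 1 / (m_da + t0)) * h_bar +
        (control$target_accept - a) / (m_da + t0)
      log_eps <- mu_da - sqrt(m_da) / gamma_da * h_bar
      eta <- m_da^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      in_slow <- control$adapt_metric && it > win$fast1 && it <= warmup - win$final
      if (in_slow) buf <- rbind(buf, theta)
      if (it %in% window_ends && !is.null(buf) && nrow(buf) >= 10) {
        v <- apply(buf, 2, stats::var)
        v[!is.finite(v) | v < 1e-10] <- 1e-10
        n <- nrow(buf)
        ## regularised metric update, then re-adapt the step size
        inv_mass <- v * n / (n + 5) + inv_mass * 5 / (n + 5)
        da_restart(exp(log_eps_bar))
        eps <- exp(mu_da) / 10
        buf <- NULL
      }
      if (it == warmup) eps <- exp(log_eps_bar)  # freeze adapted step size
    } else {
      out[it - warmup, ] <- theta
      lp_out[it - warmup] <- cache$lp
    }
  }
  list(draws = out, lp = lp_out, accept_rate = mean(accept[(warmup + 1):total]),
       n_divergent = n_div, step_size = eps)
}

#' Sample a posterior with adaptive Hamiltonian Monte Carlo
#'
#' @param lp_grad function(theta) returning `list(lp, grad)`.
#' @param init initial vector, or function(chain) returning one.
#' @param n_params parameter dimension (needed when `init` is a function).
#' @param options [mcmc_options()].
#' @param seed integer; chain c uses `seed + c`.
#' @param inv_mass0 optional warm-start diagonal inverse mass (approximate
#'   posterior variances), refined during warmup.
#' @return object of class `sbr_samples`: `draws` (iterations x params x
#'   chains array), `lp`, per-chain acceptance rates, divergence counts,
#'   step sizes, and the seed.
#' @export
run_hmc <- function(lp_grad, init, n_params = length(init),
                    options = mcmc_options(), seed = 1L, inv_mass0 = NULL) {
  chains <- vector("list", options$chains)
  for (ch in seq_len(options$chains)) {
    th0 <- if (is.function(init)) init(ch) else init
    chains[[ch]] <- hmc_chain(lp_grad, th0, options$warmup, options$draws,
                              options, seed = seed + ch, inv_mass0 = inv_mass0)
  }
  draws <- array(NA_real_, c(options$draws, n_params, options$chains))
  for (ch in seq_along(chains)) draws[, , ch] <- chains[[ch]]$draws
  div_frac <- sum(vapply(chains, `[[`, 0L, "n_divergent")) /
    (options$chains * options$draws)
  if (div_frac > options$max_divergence_frac)
    warning(sprintf("divergent-transition fraction %.1f%% exceeds %.0f%%",
                    100 * div_frac, 100 * options$max_divergence_frac),
            call. = FALSE)
  structure(list(draws = draws,
                 lp = vapply(chains, `[[`, numeric(options$draws), "lp"),
                 accept_rate = vapply(chains, `[[`, 0, "accept_rate"),
                 n_divergent = vapply(chains, `[[`, 0L, "n_divergent"),
                 step_size = vapply(chains, `[[`, 0, "step_size"),
                 seed = seed, options = options),
            class = "sbr_samples")
}

#' Split-chain potential scale reduction factor
#'
#' Splits each chain in half and computes the rank-free split-Rhat:
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-half variance
#' and `B` the between-half variance of the means.
#'
#' @param x iterations x chains matrix of draws for one parameter.
#' @return Rhat (>= 1 up to noise); NA for zero-variance draws.
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  W <- mean(apply(halves, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(halves))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Effective sample size (split chains, initial-positive-sequence)
#'
#' Combines per-half-chain autocovariances into the multi-chain correlation
#' estimate and sums paired autocorrelations until the first non-positive
#' pair (Geyer's initial positive sequence).
#'
#' @param x iterations x chains matrix of draws for one parameter.
#' @return estimated effective sample size.
#' @export
ess_mean <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(n), , drop = FALSE],
                  x[n + seq_len(n), , drop = FALSE])
  m <- ncol(halves)
  W <- mean(apply(halves, 2, stats::var))
  if (!is.finite(W) || W == 0) return(NA_real_)
  B <- n * stats::var(colMeans(halves))
  var_plus <- (n - 1) / n * W + B / n
  lag_max <- n - 2
  acov <- sapply(seq_len(m), function(j)
    stats::acf(halves[, j], lag.max = lag_max, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (W - rowMeans(acov)[-1]) / var_plus
  ## sum consecutive pairs while positive
  s <- 0; t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t] + rho[t + 1]
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    t <- t + 2
  }
  ess <- m * n / (1 + 2 * s)
  min(ess, m * n)
}

#' Convergence diagnostics for posterior samples
#'
#' Per-parameter split-Rhat and effective sample size; the report passes
#' when `max Rhat < rhat_max` and `min ESS > ess_min`.
#'
#' @param samples `sbr_samples` (>= 2 chains required).
#' @param rhat_max,ess_min pass thresholds (conventional defaults 1.05, 100).
#' @param param_names optional parameter labels.
#' @return list with the per-parameter table, summary extrema, divergence
#'   counts and a logical `pass`.
#' @export
mcmc_diagnostics <- function(samples, rhat_max = 1.05, ess_min = 100,
                             param_names = NULL) {
  stopifnot(inherits(samples, "sbr_samples"))
  if (dim(samples$draws)[3] < 2)
    stop("at least 2 chains are required for diagnostics", call. = FALSE)
  d <- dim(samples$draws)[2]
  rhat <- numeric(d); ess <- numeric(d)
  for (j in seq_len(d)) {
    xj <- samples$draws[, j, ]
    rhat[j] <- split_rhat(xj)
    ess[j] <- ess_mean(xj)
  }
  tab <- data.frame(parameter = param_names %||% paste0("theta", seq_len(d)),
                    rhat = rhat, ess = ess)
  ok <- is.finite(rhat) & is.finite(ess)
  res <- list(table = tab,
              max_rhat = max(rhat[ok]), min_ess = min(ess[ok]),
              n_divergent = sum(samples$n_divergent),
              accept_rate = mean(samples$accept_rate))
  res$pass <- res$max_rhat < rhat_max && res$min_ess > ess_min
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
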