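## Posterior sampler for the hierarchical model. The model is
## linear-Gaussian given its scale parameters, so sampling alternates three
## blocks per iteration:
##   1. the linear block (regression coefficients, intercept hierarchy,
##      spline deviations) drawn exactly from its multivariate-normal
##      conditional;
##   2. the survey bias drawn exactly from its zero-truncated normal
##      conditional;
##   3. the scale block (horseshoe local/global scales, hierarchy and
##      innovation scales, source-type error scales) updated by a
##      Hamiltonian Monte Carlo step on its log-transformed conditional,
##      with dual-averaging step-size adaptation during warmup.
## This mixes orders of magnitude faster than joint HMC here because the
## stiff, high-dimensional Gaussian directions are drawn exactly.

## Fixed design structures of the linear block:
## w = (beta(6), aw, alpha_r(R), alpha_c(C), u((K-1) per country)).
linear_structures <- function(inputs) {
  C <- inputs$n_countries; R <- inputs$n_regions; T <- inputs$n_years
  Km1 <- inputs$basis$K - 1L
  idx_beta <- 1:6
  idx_aw <- 7L
  idx_ar <- 7L + seq_len(R)
  idx_ac <- 7L + R + seq_len(C)
  u_off <- 7L + R + C
  d <- u_off + Km1 * C
  n <- length(inputs$y)
  A <- inputs$basis$A

  Z <- matrix(0, n, d)
  Z[, idx_beta] <- inputs$X[inputs$cy_idx, , drop = FALSE]
  Z[cbind(seq_len(n), idx_ac[inputs$c_idx])] <- 1
  for (i in seq_len(n))
    Z[i, u_off + (inputs$c_idx[i] - 1L) * Km1 + seq_len(Km1)] <-
      A[inputs$t_idx[i], ]

  ## latent map over the full grid, rows in (country-major, year-fastest) order
  Lmap <- matrix(0, C * T, d)
  Lmap[, idx_beta] <- inputs$X
  for (c in seq_len(C)) {
    rows <- (c - 1L) * T + seq_len(T)
    Lmap[rows, idx_ac[c]] <- 1
    Lmap[rows, u_off + (c - 1L) * Km1 + seq_len(Km1)] <- A
  }
  list(d = d, n = n, Km1 = Km1, Z = Z, Lmap = Lmap,
       idx_beta = idx_beta, idx_aw = idx_aw, idx_ar = idx_ar,
       idx_ac = idx_ac, u_off = u_off,
       obs_by_country = split(seq_len(n), factor(inputs$c_idx, seq_len(C))))
}

## Scale-block coordinates (all logs):
## llam(6), ltau, lta, ltr, ltd(C), mu_t, lst, lss(3)  -> 13 + C
scale_layout <- function(C) {
  sizes <- c(llam = 6, ltau = 1, lta = 1, ltr = 1, ltd = C, mu_t = 1,
             lst = 1, lss = 3)
  ends <- cumsum(sizes); starts <- ends - sizes + 1
  list(sizes = sizes, starts = starts, ends = ends, total = sum(sizes))
}

## beta marginal scale under the regularised horseshoe
hs_scale <- function(lam, tau, slab) {
  tau * slab * lam / sqrt(slab^2 + tau^2 * lam^2)
}

## Conditional log density + gradient of the scale block given sufficient
## statistics of the linear block and the residuals.
scale_lp_grad <- function(s, st, op) {
  lo <- st$slayout
  g <- function(n) s[lo$starts[[n]]:lo$ends[[n]]]
  llam <- g("llam"); ltau <- g("ltau"); lta <- g("lta"); ltr <- g("ltr")
  ltd <- g("ltd"); mu_t <- g("mu_t"); lst <- g("lst"); lss <- g("lss")
  lam <- exp(llam); tau <- exp(ltau); ta <- exp(lta); tr <- exp(ltr)
  td <- exp(ltd); stau <- exp(lst); sig <- exp(lss)

  q <- op$slab_scale^2 + tau^2 * lam^2
  s_b <- hs_scale(lam, tau, op$slab_scale)
  lp <- sum(-st$beta2 / (2 * s_b^2) - log(s_b)) +
    sum(-log1p(lam^2) + llam) + (-log1p((tau / op$hs_tau0)^2) + ltau)
  dls <- st$beta2 / s_b^3 - 1 / s_b            # d lp / d s_b
  ds_dlam <- tau * op$slab_scale^3 / q^1.5
  ds_dtau <- op$slab_scale^3 * lam / q^1.5
  g_llam <- dls * ds_dlam * lam + (-2 * lam^2 / (1 + lam^2) + 1)
  g_ltau <- sum(dls * ds_dtau) * tau +
    (-2 * (tau / op$hs_tau0)^2 / (1 + (tau / op$hs_tau0)^2) + 1)

  C <- length(ltd); R <- st$n_regions
  lp <- lp - st$ssq_c / (2 * ta^2) - C * log(ta) - ta^2 / (2 * op$tau_alpha_scale^2) + lta
  g_lta <- st$ssq_c / ta^2 - C - ta^2 / op$tau_alpha_scale^2 + 1
  lp <- lp - st$ssq_r / (2 * tr^2) - R * log(tr) - tr^2 / (2 * op$tau_region_scale^2) + ltr
  g_ltr <- st$ssq_r / tr^2 - R - tr^2 / op$tau_region_scale^2 + 1

  Km1 <- st$Km1
  lp <- lp + sum(-st$ssq_u / (2 * td^2) - Km1 * ltd) +
    sum(-(ltd - mu_t)^2 / (2 * stau^2)) - C * lst +
    (-(mu_t - op$mu_tau_mean)^2 / (2 * op$mu_tau_sd^2)) +
    (-stau^2 / (2 * op$sigma_tau_scale^2) + lst)
  g_ltd <- st$ssq_u / td^2 - Km1 - (ltd - mu_t) / stau^2
  g_mu_t <- sum(ltd - mu_t) / stau^2 - (mu_t - op$mu_tau_mean) / op$mu_tau_sd^2
  g_lst <- sum((ltd - mu_t)^2) / stau^2 - C -
    stau^2 / op$sigma_tau_scale^2 + 1

  g_lss <- numeric(3)
  for (k in 1:3) {
    r2 <- st$res2[[k]]; vk <- st$var_known[[k]]
    if (length(r2)) {
      v <- vk + sig[k]^2
      lp <- lp - 0.5 * sum(log(v) + r2 / v)
      g_lss[k] <- sum(r2 / v^2 - 1 / v) * sig[k]^2
    }
    lp <- lp - sig[k]^2 / (2 * op$sigma_source_scale^2) + lss[k]
    g_lss[k] <- g_lss[k] - sig[k]^2 / op$sigma_source_scale^2 + 1
  }
  list(lp = lp, grad = c(g_llam, g_ltau, g_lta, g_ltr, g_ltd, g_mu_t,
                         g_lst, g_lss))
}

## Conditional log density + gradient of (log lambda, log tau) given beta.
hs_lp_grad <- function(x7, beta2, op) {
  llam <- x7[1:6]; ltau <- x7[7]
  lam <- exp(llam); tau <- exp(ltau)
  q <- op$slab_scale^2 + tau^2 * lam^2
  s_b <- hs_scale(lam, tau, op$slab_scale)
  lp <- sum(-beta2 / (2 * s_b^2) - log(s_b)) +
    sum(-log1p(lam^2) + llam) + (-log1p((tau / op$hs_tau0)^2) + ltau)
  dls <- beta2 / s_b^3 - 1 / s_b
  g_llam <- dls * (tau * op$slab_scale^3 / q^1.5) * lam +
    (-2 * lam^2 / (1 + lam^2) + 1)
  g_ltau <- sum(dls * (op$slab_scale^3 * lam / q^1.5)) * tau +
    (-2 * (tau / op$hs_tau0)^2 / (1 + (tau / op$hs_tau0)^2) + 1)
  list(lp = lp, grad = c(g_llam, g_ltau))
}

scale_suffstats <- function(w, b, str, inputs, slayout) {
  beta <- w[str$idx_beta]
  aw <- w[str$idx_aw]; ar <- w[str$idx_ar]; ac <- w[str$idx_ac]
  u <- matrix(w[(str$u_off + 1):str$d], str$Km1)
  res <- inputs$y - as.numeric(str$Z %*% w) - b * inputs$is_survey
  res2 <- var_known <- vector("list", 3)
  for (k in 1:3) {
    sel <- inputs$source_idx == k + 1L
    res2[[k]] <- res[sel]^2
    var_known[[k]] <- inputs$var_known[sel]
  }
  list(beta2 = beta^2,
       ssq_c = sum((ac - ar[inputs$region_of])^2),
       ssq_r = sum((ar - aw)^2),
       ssq_u = colSums(u^2),
       res2 = res2, var_known = var_known,
       n_regions = inputs$n_regions, Km1 = str$Km1, slayout = slayout)
}

## Exact draw of the linear block from its Gaussian conditional.
draw_linear <- function(str, inputs, scales, b, op) {
  d <- str$d
  P <- matrix(0, d, d)
  rhs <- numeric(d)
  ib <- str$idx_beta; iw <- str$idx_aw; ir <- str$idx_ar; ic <- str$idx_ac
  diag(P)[ib] <- 1 / scales$s_beta^2
  P[iw, iw] <- 1 / op$alpha_sd^2
  rhs[iw] <- op$alpha_mean / op$alpha_sd^2
  pr <- 1 / scales$tau_region^2
  for (r in seq_along(ir)) {
    P[ir[r], ir[r]] <- P[ir[r], ir[r]] + pr
    P[iw, iw] <- P[iw, iw] + pr
    P[ir[r], iw] <- P[ir[r], iw] - pr
    P[iw, ir[r]] <- P[iw, ir[r]] - pr
  }
  pa <- 1 / scales$tau_alpha^2
  for (c in seq_along(ic)) {
    rr <- ir[inputs$region_of[c]]
    P[ic[c], ic[c]] <- P[ic[c], ic[c]] + pa
    P[rr, rr] <- P[rr, rr] + pa
    P[ic[c], rr] <- P[ic[c], rr] - pa
    P[rr, ic[c]] <- P[rr, ic[c]] - pa
  }
  pu <- rep(1 / scales$tau_delta^2, each = str$Km1)
  iu <- (str$u_off + 1):d
  diag(P)[iu] <- diag(P)[iu] + pu

  v <- inputs$var_known + scales$sig_all[inputs$source_idx]^2
  yb <- inputs$y - b * inputs$is_survey
  Zw <- str$Z / sqrt(v)
  Q <- P + crossprod(Zw)
  rhs <- rhs + as.numeric(crossprod(str$Z, yb / v))
  R <- chol(Q)
  mu <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  mu + backsolve(R, stats::rnorm(d))
}

## Exact draw of the survey bias from its zero-truncated normal conditional.
draw_bias <- function(w, str, inputs, scales, op) {
  sel <- inputs$is_survey
  prec <- 1 / op$b_survey_scale^2
  mean_num <- 0
  if (any(sel)) {
    v <- inputs$var_known[sel] + scales$sig_all[inputs$source_idx[sel]]^2
    r <- inputs$y[sel] - as.numeric(str$Z[sel, , drop = FALSE] %*% w)
    prec <- prec + sum(1 / v)
    mean_num <- sum(r / v)
  }
  m <- mean_num / prec
  s <- 1 / sqrt(prec)
  pzero <- stats::pnorm(0, m, s)
  if (pzero < 1e-12) return(0)      # numerically degenerate upper tail
  stats::qnorm(stats::runif(1) * pzero, m, s)
}

scales_from_s <- function(s, slayout, C, op) {
  g <- function(n) s[slayout$starts[[n]]:slayout$ends[[n]]]
  lam <- exp(g("llam")); tau <- exp(g("ltau"))
  sig <- exp(g("lss"))
  list(s_beta = hs_scale(lam, tau, op$slab_scale),
       hs_lambda = lam, hs_tau = tau,
       tau_alpha = exp(g("lta")), tau_region = exp(g("ltr")),
       tau_delta = exp(g("ltd")), mu_tau = g("mu_t"), sigma_tau = exp(g("lst")),
       sig_all = c(op$sigma_admin, sig))
}

## Univariate slice sampler (Neal 2003, stepping out + shrinkage).
slice_update_1d <- function(x0, lp_fun, w = 1, m = 30) {
  f0 <- lp_fun(x0)
  if (!is.finite(f0)) return(x0)
  logy <- f0 - stats::rexp(1)
  L <- x0 - w * stats::runif(1); Rr <- L + w
  j <- floor(m * stats::runif(1)); k <- m - 1 - j
  while (j > 0 && is.finite(fL <- lp_fun(L)) && fL > logy) { L <- L - w; j <- j - 1 }
  while (k > 0 && is.finite(fR <- lp_fun(Rr)) && fR > logy) { Rr <- Rr + w; k <- k - 1 }
  for (rep in 1:100) {
    x1 <- L + stats::runif(1) * (Rr - L)
    f1 <- lp_fun(x1)
    if (is.finite(f1) && f1 > logy) return(x1)
    if (x1 < x0) L <- x1 else Rr <- x1
  }
  x0
}

sbr_gibbs_chain <- function(inputs, str, warmup, draws, seed,
                            target_accept = 0.8) {
  set.seed(seed)
  op <- inputs$options
  C <- inputs$n_countries
  slayout <- scale_layout(C)
  sidx <- function(n) slayout$starts[[n]]:slayout$ends[[n]]
  i_hs <- c(sidx("llam"), sidx("ltau"))        # horseshoe block, HMC
  i_slice <- c(sidx("lta"), sidx("ltr"), sidx("ltd"), sidx("lst"), sidx("lss"))
  i_mu <- sidx("mu_t")

  ## initial scale coordinates at prior centres
  s <- c(rep(0, 6), log(op$hs_tau0), log(0.2), log(0.2),
         rep(op$mu_tau_mean, C), op$mu_tau_mean, log(0.2), rep(log(0.1), 3)) +
    stats::rnorm(slayout$total, 0, 0.1)
  b <- -abs(stats::rnorm(1, 0, op$b_survey_scale / 2))

  ## dual averaging for the horseshoe-block HMC step
  eps <- 0.1
  mu_da <- log(10 * eps); log_eps_bar <- log(eps); h_bar <- 0
  gamma_da <- 0.05; t0 <- 10; kappa <- 0.75

  total <- warmup + draws
  keep_w <- matrix(NA_real_, draws, str$d)
  keep_s <- matrix(NA_real_, draws, slayout$total)
  keep_b <- numeric(draws)
  accept <- numeric(total)
  n_div <- 0L

  for (it in seq_len(total)) {
    scales <- scales_from_s(s, slayout, C, op)
    w <- draw_linear(str, inputs, scales, b, op)
    b <- draw_bias(w, str, inputs, scales, op)
    st <- scale_suffstats(w, b, str, inputs, slayout)

    ## 1. gradient HMC on the coupled horseshoe block
    lg_hs <- function(x7) hs_lp_grad(x7, st$beta2, op)
    cache <- lg_hs(s[i_hs])
    p0 <- stats::rnorm(length(i_hs))
    n_steps <- sample(8:16, 1)
    h0 <- cache$lp - 0.5 * sum(p0^2)
    prop <- leapfrog(lg_hs, s[i_hs], p0, eps, rep(1, length(i_hs)),
                     n_steps, cache)
    if (prop$ok) {
      h1 <- prop$cache$lp - 0.5 * sum(prop$p^2)
      a <- min(1, exp(h1 - h0)); if (!is.finite(a)) a <- 0
      if ((h0 - h1) > 1000 && it > warmup) n_div <- n_div + 1L
    } else a <- 0
    if (stats::runif(1) < a) s[i_hs] <- prop$theta
    accept[it] <- a

    ## 2. exact conjugate draw of the innovation-scale mean
    ltd <- s[sidx("ltd")]; stau <- exp(s[sidx("lst")])
    prec <- C / stau^2 + 1 / op$mu_tau_sd^2
    mn <- (sum(ltd) / stau^2 + op$mu_tau_mean / op$mu_tau_sd^2) / prec
    s[i_mu] <- stats::rnorm(1, mn, 1 / sqrt(prec))

    ## 3. robust univariate slice updates for the remaining scales, each on
    ##    its own conditional density (only the terms involving it)
    Km1 <- st$Km1
    s[sidx("lta")] <- slice_update_1d(s[sidx("lta")], function(x) {
      ta2 <- exp(2 * x)
      -st$ssq_c / (2 * ta2) - C * x - ta2 / (2 * op$tau_alpha_scale^2) + x
    }, w = 0.8)
    s[sidx("ltr")] <- slice_update_1d(s[sidx("ltr")], function(x) {
      tr2 <- exp(2 * x)
      -st$ssq_r / (2 * tr2) - st$n_regions * x -
        tr2 / (2 * op$tau_region_scale^2) + x
    }, w = 0.8)
    mu_now <- s[i_mu]; st2 <- exp(2 * s[sidx("lst")])
    ii <- sidx("ltd")
    for (c in seq_len(C)) {
      ssq <- st$ssq_u[c]
      s[ii[c]] <- slice_update_1d(s[ii[c]], function(x)
        -ssq / (2 * exp(2 * x)) - Km1 * x - (x - mu_now)^2 / (2 * st2),
        w = 0.8)
    }
    ltd2 <- s[sidx("ltd")]
    ssq_ltd <- sum((ltd2 - mu_now)^2)
    s[sidx("lst")] <- slice_update_1d(s[sidx("lst")], function(x) {
      v <- exp(2 * x)
      -ssq_ltd / (2 * v) - C * x - v / (2 * op$sigma_tau_scale^2) + x
    }, w = 0.8)
    jj <- sidx("lss")
    for (k in 1:3) {
      r2 <- st$res2[[k]]; vk <- st$var_known[[k]]
      s[jj[k]] <- slice_update_1d(s[jj[k]], function(x) {
        sg2 <- exp(2 * x)
        lp <- -sg2 / (2 * op$sigma_source_scale^2) + x
        if (length(r2)) {
          v <- vk + sg2
          lp <- lp - 0.5 * sum(log(v) + r2 / v)
        }
        lp
      }, w = 0.8)
    }

    ## 4. interweaving move for the innovation scales (ancillary form):
    ##    with the scaled path shape eps_c = u_c / tau_c held fixed, tau_c's
    ##    conditional is likelihood-informed, which breaks the centred
    ##    funnel for data-rich countries.
    mu_now <- s[i_mu]; st2 <- exp(2 * s[sidx("lst")])
    sig_all <- c(op$sigma_admin, exp(s[jj]))
    res_full <- inputs$y - as.numeric(str$Z %*% w) - b * inputs$is_survey
    v_all <- inputs$var_known + sig_all[inputs$source_idx]^2
    for (c in seq_len(C)) {
      oc <- str$obs_by_country[[c]]
      if (!length(oc)) next
      iu <- str$u_off + (c - 1L) * Km1 + seq_len(Km1)
      tau_old <- exp(s[ii[c]])
      eps_c <- w[iu] / tau_old
      p_i <- as.numeric(inputs$basis$A[inputs$t_idx[oc], , drop = FALSE] %*% eps_c)
      r_i <- res_full[oc] + tau_old * p_i
      v_i <- v_all[oc]
      lnew <- slice_update_1d(s[ii[c]], function(x)
        -0.5 * sum((r_i - exp(x) * p_i)^2 / v_i) - (x - mu_now)^2 / (2 * st2),
        w = 0.8)
      if (lnew != s[ii[c]]) {
        s[ii[c]] <- lnew
        w[iu] <- exp(lnew) * eps_c
      }
    }

    ## matching interweaved moves for the hyper-pair (mu_tau, sigma_tau):
    ## with the standardised scales zeta_c = (ltd_c - mu)/sigma held fixed,
    ## their conditionals see the path-magnitude information directly.
    uw <- matrix(w[(str$u_off + 1):str$d], Km1)
    ssq_u2 <- colSums(uw^2)
    ltd_cur <- s[ii]; mu_cur <- s[i_mu]; st_cur <- exp(s[sidx("lst")])
    zeta <- (ltd_cur - mu_cur) / st_cur
    s[sidx("lst")] <- slice_update_1d(s[sidx("lst")], function(x) {
      ltd_x <- mu_cur + exp(x) * zeta
      sum(-ssq_u2 / (2 * exp(2 * ltd_x)) - Km1 * ltd_x) -
        exp(2 * x) / (2 * op$sigma_tau_scale^2) + x
    }, w = 0.5)
    st_cur <- exp(s[sidx("lst")])
    s[i_mu] <- slice_update_1d(mu_cur, function(x) {
      ltd_x <- x + st_cur * zeta
      sum(-ssq_u2 / (2 * exp(2 * ltd_x)) - Km1 * ltd_x) -
        (x - op$mu_tau_mean)^2 / (2 * op$mu_tau_sd^2)
    }, w = 0.5)
    s[ii] <- s[i_mu] + st_cur * zeta

    if (it <= warmup) {
      h_bar <- (1 - 1 / (it + t0)) * h_bar + (target_accept - a) / (it + t0)
      log_eps <- mu_da - sqrt(it) / gamma_da * h_bar
      eta <- it^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      keep_w[it - warmup, ] <- w
      keep_s[it - warmup, ] <- s
      keep_b[it - warmup] <- b
    }
  }
  list(w = keep_w, s = keep_s, b = keep_b,
       accept_rate = mean(accept[(warmup + 1):total]),
       n_divergent = n_div, step_size = eps)
}

#' Sample the stillbirth-rate model posterior
#'
#' Blocked MCMC: exact multivariate-normal draws for the linear block,
#' an exact truncated-normal draw for the survey bias, and a gradient-based
#' HMC step for the scale block conditional (see the package vignette).
#'
#' @param inputs `sbr_model_inputs`.
#' @param options [mcmc_options()] (chains, warmup, draws, target_accept).
#' @param seed integer; chain c uses `seed + c`.
#' @return `sbr_samples` whose parameter columns are the linear block, the
#'   survey bias and the log-scale block, with a `columns` attribute naming
#'   the blocks.
#' @export
run_sbr_mcmc <- function(inputs, options = mcmc_options(), seed = 1L) {
  str <- linear_structures(inputs)
  slayout <- scale_layout(inputs$n_countries)
  d_all <- str$d + 1L + slayout$total
  chains <- vector("list", options$chains)
  for (ch in seq_len(options$chains))
    chains[[ch]] <- sbr_gibbs_chain(inputs, str, options$warmup, options$draws,
                                    seed = seed + ch,
                                    target_accept = options$target_accept)
  draws <- array(NA_real_, c(options$draws, d_all, options$chains))
  for (ch in seq_along(chains))
    draws[, , ch] <- cbind(chains[[ch]]$w, chains[[ch]]$b, chains[[ch]]$s)
  structure(list(draws = draws,
                 lp = NULL,
                 accept_rate = vapply(chains, `[[`, 0, "accept_rate"),
                 n_divergent = vapply(chains, `[[`, 0L, "n_divergent"),
                 step_size = vapply(chains, `[[`, 0, "step_size"),
                 seed = seed, options = options,
                 structures = str, scale_layout = slayout),
            class = "sbr_samples")
}

sbr_sample_param_names <- function(inputs, str, slayout) {
  C <- inputs$n_countries
  nm <- c(paste0("beta_", design_columns()), "alpha_w",
          paste0("alpha_r[", inputs$regions, "]"),
          paste0("alpha_c[", inputs$countries, "]"),
          paste0("u[", rep(inputs$countries, each = str$Km1), ",",
                 rep(seq_len(str$Km1), C), "]"),
          "b_survey")
  snm <- character(0)
  for (bk in names(slayout$sizes))
    snm <- c(snm, if (slayout$sizes[[bk]] == 1) bk
             else paste0(bk, "[", seq_len(slayout$sizes[[bk]]), "]"))
  c(nm, snm)
}
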