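# Bayesian estimation of the weighted-average localization model and the
# binomial discrimination model.
#
# Localization likelihood (one subject, conditions c = (fm, dL) cells):
#   singles:  R_i ~ Normal(g*T_i + b, sigma_s)
#   doubles:  R_j ~ Normal(g*(w_c*T_j + (1-w_c)*D_j) + b, sigma_d[c])
# with g, b, sigma_s shared across all (interleaved) trials and w_c,
# sigma_d[c] per condition. Priors: b ~ Normal(0, 10), g ~ Normal(1, 10),
# sigma ~ Gamma(shape, rate) on every SD, w ~ Beta(1, 1).
#
# The sampler is Metropolis-within-Gibbs: g, b and each w have exact
# (truncated-)normal full conditionals; the SDs are updated by univariate
# slice sampling on log(sigma). Chains differ only by seed/initialization
# (prior draws).

#' Prior specification for the localization model
#'
#' @param prior_g,prior_b Length-2 `(mean, sd)` of the normal priors on
#'   gain and bias.
#' @param prior_sigma Length-2 `(shape, rate)` of the Gamma prior placed
#'   on every response SD (both `sigma_s` and each `sigma_d`). The default
#'   Gamma(1, 0.04) has mean 25 deg and is effectively flat over 0-50 deg.
#' @param prior_w Length-2 Beta parameters of the weight prior; the
#'   uniform Beta(1, 1) keeps `w` in `[0, 1]` without shaping it.
#' @return A list of class `localization_model_spec`.
#' @export
localization_model_spec <- function(prior_g = c(mean = 1, sd = 10),
                                    prior_b = c(mean = 0, sd = 10),
                                    prior_sigma = c(shape = 1, rate = 0.04),
                                    prior_w = c(1, 1)) {
  stopifnot(prior_g[2] > 0, prior_b[2] > 0, all(prior_sigma > 0),
            all(prior_w > 0))
  structure(list(prior_g = unname(prior_g), prior_b = unname(prior_b),
                 prior_sigma = unname(prior_sigma),
                 prior_w = unname(prior_w)),
            class = "localization_model_spec")
}

# --- sampler internals ------------------------------------------------------

# Truncated Normal(m, s) on [0, 1]; exponential-tilt fallback when the
# untruncated mass on [0, 1] underflows.
rtnorm01 <- function(m, s) {
  plo <- stats::pnorm(0, m, s)
  phi <- stats::pnorm(1, m, s)
  if (phi - plo > 1e-12) {
    return(min(max(stats::qnorm(stats::runif(1, plo, phi), m, s), 0), 1))
  }
  if (m >= 1) {
    lam <- (m - 1) / s^2 + 1e-12
    repeat { d <- stats::rexp(1, lam); if (d <= 1) return(1 - d) }
  }
  lam <- -m / s^2 + 1e-12
  repeat { d <- stats::rexp(1, lam); if (d <= 1) return(d) }
}

# Univariate slice sampler (stepping out + shrinkage), Neal (2003).
slice_sample1 <- function(x0, logf, w = 1, max_steps = 50) {
  logy <- logf(x0) - stats::rexp(1)
  u <- stats::runif(1) * w
  L <- x0 - u
  R <- L + w
  k <- max_steps
  while (k > 0 && logf(L) > logy) { L <- L - w; k <- k - 1 }
  k <- max_steps
  while (k > 0 && logf(R) > logy) { R <- R + w; k <- k - 1 }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= logy) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
  }
}

# Slice update of log(sigma): posterior with n residuals of sum of
# squares SS and Gamma(shape, rate) prior on sigma itself.
update_log_sigma <- function(lsig, n, SS, shape, rate) {
  logf <- function(lx) {
    (shape - n) * lx - rate * exp(lx) - SS / 2 * exp(-2 * lx)
  }
  # floor keeps the conditional proper when residuals are exactly zero
  max(slice_sample1(lsig, logf, w = 0.5), log(1e-6))
}

# One MCMC chain for the joint localization model.
# dat: list(Ts, Rs, Td, Dd, Rd, cid, nc) with cid the condition index of
# each double trial (possibly zero-length vectors).
run_wa_chain <- function(dat, spec, n_samples, n_burn, seed) {
  withr::with_seed(as.integer(seed), {
    nc <- dat$nc
    ns <- length(dat$Ts)
    nd <- length(dat$Td)
    n_per_cond <- if (nc) tabulate(dat$cid, nc) else integer(0)
    uniform_w <- all(spec$prior_w == 1)
    g <- stats::rnorm(1, spec$prior_g[1], spec$prior_g[2])
    b <- stats::rnorm(1, spec$prior_b[1], spec$prior_b[2])
    sig_s <- max(stats::rgamma(1, spec$prior_sigma[1], spec$prior_sigma[2]),
                 0.5)
    w <- if (nc) stats::rbeta(nc, spec$prior_w[1], spec$prior_w[2]) else
      numeric(0)
    sig_d <- pmax(stats::rgamma(nc, spec$prior_sigma[1],
                                spec$prior_sigma[2]), 0.5)
    shape <- spec$prior_sigma[1]
    rate <- spec$prior_sigma[2]
    pg <- spec$prior_g
    pb <- spec$prior_b
    diffd <- dat$Td - dat$Dd
    n_kept <- n_samples - n_burn
    draws <- matrix(NA_real_, n_kept, 3 + 2 * nc)
    for (it in seq_len(n_samples)) {
      if (nc) {
        wv <- w[dat$cid]
        sv <- sig_d[dat$cid]
        for (c in seq_len(nc)) {
          jc <- dat$cid == c
          a <- g * diffd[jc]
          y <- dat$Rd[jc] - g * dat$Dd[jc] - b
          denom <- sum(a^2)
          if (denom < 1e-12) {
            w[c] <- stats::rbeta(1, spec$prior_w[1], spec$prior_w[2])
          } else if (uniform_w) {
            w[c] <- rtnorm01(sum(a * y) / denom, sig_d[c] / sqrt(denom))
          } else {
            m <- sum(a * y) / denom
            s <- sig_d[c] / sqrt(denom)
            lf <- function(x) {
              if (x <= 0 || x >= 1) return(-Inf)
              -(x - m)^2 / (2 * s^2) +
                (spec$prior_w[1] - 1) * log(x) +
                (spec$prior_w[2] - 1) * log1p(-x)
            }
            w[c] <- slice_sample1(w[c], lf, w = 0.25)
          }
        }
        wv <- w[dat$cid]
        xd <- wv * dat$Td + (1 - wv) * dat$Dd
        isv2 <- 1 / sv^2
      } else {
        xd <- numeric(0)
        isv2 <- numeric(0)
      }
      # gain
      prec <- 1 / pg[2]^2 + sum(dat$Ts^2) / sig_s^2 + sum(xd^2 * isv2)
      num <- pg[1] / pg[2]^2 + sum(dat$Ts * (dat$Rs - b)) / sig_s^2 +
        sum(xd * (dat$Rd - b) * isv2)
      g <- stats::rnorm(1, num / prec, 1 / sqrt(prec))
      # bias
      prec <- 1 / pb[2]^2 + ns / sig_s^2 + sum(isv2)
      num <- pb[1] / pb[2]^2 + sum(dat$Rs - g * dat$Ts) / sig_s^2 +
        sum((dat$Rd - g * xd) * isv2)
      b <- stats::rnorm(1, num / prec, 1 / sqrt(prec))
      # single-sound SD
      if (ns) {
        SS <- sum((dat$Rs - g * dat$Ts - b)^2)
        sig_s <- exp(update_log_sigma(log(sig_s), ns, SS, shape, rate))
      } else {
        sig_s <- stats::rgamma(1, shape, rate)
      }
      # per-condition double-sound SDs
      if (nc) {
        res_d <- dat$Rd - g * xd - b
        for (c in seq_len(nc)) {
          SSc <- sum(res_d[dat$cid == c]^2)
          sig_d[c] <- exp(update_log_sigma(log(sig_d[c]), n_per_cond[c],
                                           SSc, shape, rate))
        }
      }
      if (it > n_burn)
        draws[it - n_burn, ] <- c(g, b, sig_s, w, sig_d)
    }
    draws
  })
}

new_wa_posterior <- function(chain_draws, par_names, conditions, n_chains,
                             n_samples, n_burn, seed) {
  draws <- lapply(seq_along(par_names), function(p) {
    m <- vapply(chain_draws, function(d) d[, p], numeric(nrow(chain_draws[[1]])))
    matrix(m, ncol = n_chains)
  })
  names(draws) <- par_names
  structure(list(draws = draws, conditions = conditions,
                 n_chains = n_chains, n_samples = n_samples,
                 n_burn = n_burn, seed = seed),
            class = "wa_posterior")
}

#' @export
print.wa_posterior <- function(x, ...) {
  cat(sprintf(
    "<wa_posterior: %d parameters, %d chains x %d kept samples (burn-in %d)>\n",
    length(x$draws), x$n_chains, nrow(x$draws[[1]]), x$n_burn))
  print(summary(x), n = Inf)
  invisible(x)
}

#' Summarize a posterior
#'
#' @param object A `wa_posterior`.
#' @param mass HDI probability mass.
#' @param ... Unused.
#' @return A tibble with `parameter`, `mean`, `sd`, `hdi_lo`, `hdi_hi`,
#'   `rhat` (NA when only one chain, e.g. after pooling).
#' @export
summary.wa_posterior <- function(object, mass = 0.95, ...) {
  rows <- lapply(names(object$draws), function(p) {
    m <- object$draws[[p]]
    x <- as.numeric(m)
    h <- hdi(x, mass)
    tibble::tibble(parameter = p, mean = mean(x), sd = stats::sd(x),
                   hdi_lo = h[1], hdi_hi = h[2],
                   rhat = if (ncol(m) >= 2) gelman_rubin(m) else NA_real_)
  })
  do.call(rbind, rows)
}

cond_par <- function(prefix, fm, dl) {
  sprintf("%s[fm=%g,dL=%g]", prefix, fm, dl)
}

#' Fit the joint localization model by MCMC
#'
#' Estimates the shared gain, bias and single-sound SD together with a
#' target weight and double-sound SD per (modulation frequency, level
#' difference) condition, from one subject's interleaved single- and
#' double-sound trials. Multiple chains are run from independent prior
#' draws; convergence should be checked with [gelman_rubin()] (reported
#' in the summary).
#'
#' @param trials A `trial_table` containing single and double trials.
#' @param responses A response tibble with `index` and `response_el`
#'   (e.g. from [simulate_localization()]), joined to `trials` by `index`.
#' @param spec A [localization_model_spec()].
#' @param n_chains,n_samples,n_burn MCMC layout; defaults 3 chains of
#'   10000 samples with the first 5000 discarded.
#' @param seed Integer seed; chains derive independent sub-seeds.
#' @return A `wa_posterior` with parameters `g`, `b`, `sigma_s` and, per
#'   condition, `w[fm=..,dL=..]` and `sigma_d[fm=..,dL=..]`; the
#'   `$conditions` tibble maps conditions to parameter names.
#' @export
fit_localization <- function(trials, responses,
                             spec = localization_model_spec(),
                             n_chains = 3, n_samples = 10000, n_burn = 5000,
                             seed = 1L) {
  stopifnot(n_burn < n_samples, n_chains >= 1)
  r <- responses$response_el[match(trials$index, responses$index)]
  if (anyNA(r) || any(!is.finite(r)))
    stop("non-finite or missing responses for some trials")
  is_d <- trials$trial_type == "double"
  if (!any(is_d)) stop("no double-sound trials")
  conds <- unique(trials[is_d, c("fm_hz", "delta_l_db")])
  conds <- conds[order(conds$fm_hz, conds$delta_l_db), ]
  cid <- match(paste(trials$fm_hz[is_d], trials$delta_l_db[is_d]),
               paste(conds$fm_hz, conds$delta_l_db))
  n_cell <- tabulate(cid, nrow(conds))
  if (any(n_cell < 2))
    stop("empty or near-empty condition cell(s): ",
         paste(cond_par("w", conds$fm_hz, conds$delta_l_db)[n_cell < 2],
               collapse = ", "))
  dat <- list(Ts = trials$target_el[!is_d], Rs = r[!is_d],
              Td = trials$target_el[is_d], Dd = trials$distractor_el[is_d],
              Rd = r[is_d], cid = cid, nc = nrow(conds))
  chain_seeds <- derive_seeds(seed, n_chains, salt = 21L)
  chains <- lapply(chain_seeds, function(s)
    run_wa_chain(dat, spec, n_samples, n_burn, s))
  par_names <- c("g", "b", "sigma_s",
                 cond_par("w", conds$fm_hz, conds$delta_l_db),
                 cond_par("sigma_d", conds$fm_hz, conds$delta_l_db))
  cond_tbl <- tibble::tibble(
    fm_hz = conds$fm_hz, delta_l_db = conds$delta_l_db,
    w_param = cond_par("w", conds$fm_hz, conds$delta_l_db),
    sigma_param = cond_par("sigma_d", conds$fm_hz, conds$delta_l_db))
  new_wa_posterior(chains, par_names, cond_tbl, n_chains, n_samples,
                   n_burn, seed)
}

#' Bayesian simple linear regression of responses on one predictor
#'
#' Fits `response ~ Normal(g * predictor + b, sigma)` with the same priors
#' as the localization model. Used for predictor-response rows: target
#' location, distractor location, or the weighted-average prediction.
#'
#' @param predictor_el Predictor values (deg), e.g. target elevations or
#'   [wa_predict()] outputs.
#' @param responses Paired response elevations (deg).
#' @inheritParams fit_localization
#' @return A `wa_posterior` with parameters `g`, `b`, `sigma_s`.
#' @export
fit_single_predictor <- function(predictor_el, responses,
                                 spec = localization_model_spec(),
                                 n_chains = 3, n_samples = 4000,
                                 n_burn = 1000, seed = 1L) {
  if (length(predictor_el) != length(responses))
    stop("predictor and response lengths differ")
  if (length(responses) < 3) stop("need at least 3 paired observations")
  if (any(!is.finite(predictor_el)) || any(!is.finite(responses)))
    stop("non-finite predictor or response values")
  dat <- list(Ts = as.numeric(predictor_el), Rs = as.numeric(responses),
              Td = numeric(0), Dd = numeric(0), Rd = numeric(0),
              cid = integer(0), nc = 0L)
  chain_seeds <- derive_seeds(seed, n_chains, salt = 22L)
  chains <- lapply(chain_seeds, function(s)
    run_wa_chain(dat, spec, n_samples, n_burn, s))
  new_wa_posterior(chains, c("g", "b", "sigma_s"),
                   tibble::tibble(fm_hz = numeric(0),
                                  delta_l_db = numeric(0),
                                  w_param = character(0),
                                  sigma_param = character(0)),
                   n_chains, n_samples, n_burn, seed)
}

# --- discrimination ---------------------------------------------------------

beta_hdi <- function(a, b, mass = 0.95) {
  if (a <= 1 && b <= 1) {
    p <- (1 - mass) / 2
    return(c(stats::qbeta(p, a, b), stats::qbeta(1 - p, a, b)))
  }
  if (a <= 1) return(c(0, stats::qbeta(mass, a, b)))
  if (b <= 1) return(c(stats::qbeta(1 - mass, a, b), 1))
  width <- function(p) stats::qbeta(p + mass, a, b) - stats::qbeta(p, a, b)
  p0 <- stats::optimize(width, c(0, 1 - mass))$minimum
  c(stats::qbeta(p0, a, b), stats::qbeta(p0 + mass, a, b))
}

# Random-walk Metropolis for theta on the logit scale (uniform prior).
theta_mcmc <- function(K, N, n_samples = 20000, n_burn = 2000, seed = 1L,
                       step = 0.6) {
  withr::with_seed(as.integer(seed), {
    logpost <- function(x) {
      th <- stats::plogis(x)
      K * log(th) + (N - K) * log1p(-th) + log(th) + log1p(-th)
    }
    x <- 0
    lp <- logpost(x)
    out <- numeric(n_samples)
    for (i in seq_len(n_samples)) {
      xp <- x + stats::rnorm(1, 0, step)
      lpp <- logpost(xp)
      if (log(stats::runif(1)) < lpp - lp) { x <- xp; lp <- lpp }
      out[i] <- x
    }
    stats::plogis(out[(n_burn + 1):n_samples])
  })
}

#' Fit the binomial discrimination model
#'
#' Under the uniform Beta(1, 1) prior on the correct-identification rate
#' `theta`, `K` correct out of `N` trials gives the exact conjugate
#' posterior Beta(K+1, N-K+1). The Savage-Dickey Bayes factor contrasts
#' H1: theta != 0.5 against the chance null H0: theta = 0.5. An MCMC path
#' is available for cross-checking the conjugate result.
#'
#' @param K Number of correct identifications, `0 <= K <= N`.
#' @param N Number of trials.
#' @param method `"analytic"` (conjugate; default) or `"mcmc"`.
#' @param mass HDI probability mass.
#' @param n_samples,n_burn,seed MCMC layout for `method = "mcmc"`.
#' @return A list of class `discrimination_result`: `K`, `N`, posterior
#'   `alpha`, `beta`, `theta_mean`, `theta_sd`, `hdi` (length 2), `bf10`
#'   (a `bayes_factor` with evidence label), and `samples` for the MCMC
#'   path.
#' @export
fit_discrimination <- function(K, N, method = c("analytic", "mcmc"),
                               mass = 0.95, n_samples = 20000,
                               n_burn = 2000, seed = 1L) {
  method <- match.arg(method)
  if (K < 0 || K > N) stop("need 0 <= K <= N")
  a <- K + 1
  b <- N - K + 1
  if (method == "analytic") {
    res <- list(K = K, N = N, alpha = a, beta = b,
                theta_mean = a / (a + b),
                theta_sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))),
                hdi = beta_hdi(a, b, mass),
                bf10 = savage_dickey_bf(stats::dbeta(0.5, a, b), 1),
                samples = NULL)
  } else {
    s <- theta_mcmc(K, N, n_samples, n_burn, seed)
    res <- list(K = K, N = N, alpha = a, beta = b,
                theta_mean = mean(s), theta_sd = stats::sd(s),
                hdi = hdi(s, mass),
                bf10 = savage_dickey_samples(s, 0.5, 1),
                samples = s)
  }
  class(res) <- "discrimination_result"
  res
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "<discrimination: K=%d/%d, theta = %.3f [%.3f, %.3f], BF10 = %.3g (%s)>\n",
    x$K, x$N, x$theta_mean, x$hdi[1], x$hdi[2], as.numeric(x$bf10),
    attr(x$bf10, "label")))
  invisible(x)
}

# --- generic posterior utilities --------------------------------------------

#' Highest-density interval of a sample
#'
#' The shortest contiguous interval containing `mass` of the sorted
#' samples. `mass = 1` returns the sample range.
#'
#' @param samples Numeric vector of posterior draws.
#' @param mass Probability mass in `(0, 1]`.
#' @return Length-2 numeric `(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass > 1)
    stop("mass must lie in (0, 1]")
  x <- sort(samples[is.finite(samples)])
  n <- length(x)
  if (n < 2) stop("need at least 2 finite samples")
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k):n] - x[1:(n - k + 1)]
  i <- which.min(widths)
  c(x[i], x[i + k - 1])
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computed from the between- and within-chain variances:
#' `sqrt((((n-1)/n) * W + B/n) / W)`. Values near 1 indicate convergence;
#' the conventional acceptance bound is 1.1.
#'
#' @param x A matrix (iterations x chains, >= 2 chains), a list of
#'   equal-length chain vectors, or a `wa_posterior` (returns one value
#'   per parameter).
#' @return Numeric R-hat value(s).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "wa_posterior"))
    return(vapply(x$draws, gelman_rubin, numeric(1)))
  if (is.list(x)) x <- do.call(cbind, x)
  if (!is.matrix(x) || ncol(x) < 2)
    stop("need at least 2 chains to compute the Gelman-Rubin diagnostic")
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(colMeans(x))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Savage-Dickey Bayes factor for a nested point hypothesis
#'
#' For a point null nested in the alternative, `BF10` equals the ratio of
#' prior to posterior density at the null value. Values above 1 favor the
#' alternative; the conventional evidence labels are substantial
#' (3-10), strong (10-30), very strong (30-100) and decisive (>100).
#'
#' @param posterior_density Posterior density at the null point.
#' @param prior_density Prior density at the null point (> 0; a null
#'   with zero prior density is not nested).
#' @return A numeric `bayes_factor` with a `label` attribute (see
#'   [bf_label()]).
#' @export
savage_dickey_bf <- function(posterior_density, prior_density) {
  if (!is.finite(prior_density) || prior_density <= 0)
    stop("prior density at the null point must be positive")
  if (posterior_density < 0) stop("posterior density must be >= 0")
  if (posterior_density == 0)
    warning("zero posterior density at the null point; BF10 is infinite")
  bf <- prior_density / posterior_density
  structure(bf, label = bf_label(bf), class = "bayes_factor")
}

#' Savage-Dickey Bayes factor from posterior samples
#'
#' Estimates the posterior density at the null point by Gaussian kernel
#' density estimation (Silverman's rule-of-thumb bandwidth) and applies
#' [savage_dickey_bf()]. Validated against the analytic conjugate Beta
#' case.
#'
#' @param samples Posterior draws.
#' @param null_value The nested null point.
#' @param prior_density Prior density at `null_value`.
#' @return A `bayes_factor`.
#' @export
savage_dickey_samples <- function(samples, null_value, prior_density) {
  d <- stats::density(samples, bw = "nrd0")
  post <- stats::approx(d$x, d$y, xout = null_value, yleft = 0,
                        yright = 0)$y
  savage_dickey_bf(post, prior_density)
}

#' Evidence label for a Bayes factor
#'
#' Classification thresholds at 3, 10, 30 and 100: `"anecdotal"` (1/3 to
#' 3), `"substantial"`, `"strong"`, `"very strong"`, `"decisive"`;
#' `"favors null"` below 1/3.
#'
#' @param bf10 Numeric Bayes factor(s).
#' @return Character label(s).
#' @export
bf_label <- function(bf10) {
  vapply(as.numeric(bf10), function(b) {
    if (b > 100) "decisive"
    else if (b > 30) "very strong"
    else if (b > 10) "strong"
    else if (b > 3) "substantial"
    else if (b >= 1 / 3) "anecdotal"
    else "favors null"
  }, character(1))
}

#' @export
print.bayes_factor <- function(x, ...) {
  cat(sprintf("BF10 = %.4g (%s)\n", as.numeric(x), attr(x, "label")))
  invisible(x)
}

#' Pool posteriors across subjects
#'
#' Concatenates the MCMC samples of each parameter across subjects (the
#' group summary pools samples, not parameters); group means and HDIs are
#' then computed on the pooled draws.
#'
#' @param posteriors A list of `wa_posterior` objects sharing parameter
#'   names.
#' @return A `wa_posterior` whose draws hold the pooled samples in a
#'   single column (R-hat is not defined for the pool and reported NA).
#' @export
pool_posteriors <- function(posteriors) {
  stopifnot(length(posteriors) >= 1)
  pn <- names(posteriors[[1]]$draws)
  for (p in posteriors)
    if (!setequal(names(p$draws), pn))
      stop("posteriors have mismatched parameter names")
  draws <- lapply(pn, function(nm) {
    matrix(unlist(lapply(posteriors, function(p) as.numeric(p$draws[[nm]]))),
           ncol = 1)
  })
  names(draws) <- pn
  structure(list(draws = draws, conditions = posteriors[[1]]$conditions,
                 n_chains = 1L,
                 n_samples = sum(vapply(posteriors, function(p)
                   nrow(p$draws[[1]]) * p$n_chains, numeric(1))),
                 n_burn = 0L, seed = NA_integer_),
            class = "wa_posterior")
}
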