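# Bayesian machinery: HDI, Gelman-Rubin, Savage-Dickey, conjugate and
# MCMC discrimination fits, and the localization Gibbs sampler.

test_that("hdi finds the shortest interval", {
  x <- withr::with_seed(1, rnorm(50000))
  h <- hdi(x, 0.95)
  expect_equal(h[1], qnorm(0.025), tolerance = 0.05)
  expect_equal(h[2], qnorm(0.975), tolerance = 0.05)
  expect_equal(hdi(x, 1), range(x))
  # skewed case against a density-grid oracle
  y <- withr::with_seed(2, rbeta(100000, 2, 8))
  hy <- hdi(y, 0.95)
  grid <- seq(0, 1, 1e-5)
  d <- dbeta(grid, 2, 8)
  o <- order(d, decreasing = TRUE)
  top <- grid[o[seq_len(which(cumsum(d[o]) / sum(d) >= 0.95)[1])]]
  expect_equal(hy[1], min(top), tolerance = 0.02)
  expect_equal(hy[2], max(top), tolerance = 0.02)
  expect_error(hdi(x, 0), "mass")
  expect_error(hdi(x, 1.2), "mass")
})

test_that("Gelman-Rubin diagnostic separates converged from divergent chains", {
  ch <- withr::with_seed(3, matrix(rnorm(15000), ncol = 3))
  expect_lt(gelman_rubin(ch), 1.01)
  same <- cbind(ch[, 1], ch[, 1])
  expect_equal(gelman_rubin(same), 1, tolerance = 1e-3)
  apart <- withr::with_seed(4, cbind(rnorm(1000, 0), rnorm(1000, 10)))
  expect_gt(gelman_rubin(apart), 3)
  expect_error(gelman_rubin(ch[, 1, drop = FALSE]), "2 chains")
  # agrees with the coda implementation on well-behaved chains
  mc <- coda::mcmc.list(lapply(1:3, function(i) coda::mcmc(ch[, i])))
  expect_equal(gelman_rubin(ch),
               unname(coda::gelman.diag(mc)$psrf[1, 1]), tolerance = 0.01)
})

test_that("Savage-Dickey Bayes factors agree with marginal-likelihood integration", {
  expect_equal(as.numeric(savage_dickey_bf(1, 1)), 1)
  # Beta(1,1) prior + 10/20 successes -> Beta(11,11) posterior at 0.5
  bf_sd <- savage_dickey_bf(dbeta(0.5, 11, 11), 1)
  bf_ml <- (1 / 21) / dbinom(10, 20, 0.5)
  expect_equal(as.numeric(bf_sd), bf_ml, tolerance = 1e-9)
  expect_error(savage_dickey_bf(1, 0), "prior")
  expect_equal(bf_label(5), "substantial")
  expect_equal(bf_label(c(0.1, 2, 15, 50, 500)),
               c("favors null", "anecdotal", "strong", "very strong",
                 "decisive"))
  # KDE route validated against the analytic Beta case
  s <- withr::with_seed(5, rbeta(40000, 11, 11))
  expect_equal(as.numeric(savage_dickey_samples(s, 0.5, 1)),
               as.numeric(bf_sd), tolerance = 0.05)
})

test_that("discrimination fit is the exact conjugate Beta posterior", {
  r0 <- fit_discrimination(0, 0)
  expect_equal(r0$theta_mean, 0.5)
  expect_equal(as.numeric(r0$bf10), 1)
  r <- fit_discrimination(20, 20)
  expect_equal(r$theta_mean, 21 / 22)
  expect_gt(r$hdi[1], 0.5)
  expect_error(fit_discrimination(5, 4), "K <= N")
})

test_that("MCMC theta posterior matches the conjugate moments", {
  K <- 30; N <- 160
  r <- suppressWarnings(fit_discrimination(K, N, method = "mcmc", seed = 11))
  exact_mean <- (K + 1) / (N + 2)
  exact_sd <- sqrt((K + 1) * (N - K + 1) / ((N + 2)^2 * (N + 3)))
  # Monte-Carlo SE from batch means of the chain itself
  nb <- 30
  bm <- colMeans(matrix(r$samples[seq_len(nb * (length(r$samples) %/% nb))],
                        ncol = nb))
  se <- sd(bm) / sqrt(nb)
  expect_lt(abs(r$theta_mean - exact_mean), 3 * se)
  expect_lt(abs(r$theta_sd - exact_sd), 3 * exact_sd / sqrt(200))
})

test_that("with no data every marginal reproduces its prior", {
  dat <- list(Ts = numeric(0), Rs = numeric(0), Td = numeric(0),
              Dd = numeric(0), Rd = numeric(0), cid = integer(0), nc = 1L)
  spec <- localization_model_spec()
  dr <- waloc:::run_wa_chain(dat, spec, 6000, 1000, seed = 8)
  thin <- seq(1, nrow(dr), by = 5)
  expect_gt(ks.test(dr[thin, 1], pnorm, 1, 10)$p.value, 0.01)   # g
  expect_gt(ks.test(dr[thin, 2], pnorm, 0, 10)$p.value, 0.01)   # b
  expect_gt(ks.test(dr[thin, 4], punif)$p.value, 0.01)          # w
  expect_gt(ks.test(dr[thin, 5], pgamma, 1, 0.04)$p.value, 0.01) # sigma_d
})

test_that("the localization fit recovers known generating parameters", {
  trials <- make_cell_trials()
  resp <- simulate_localization(
    trials, cell_params(w = 0.5, g = 1, b = 0, sigma_s = 8, sigma_d = 10),
    seed = 21)
  post <- fit_localization(trials, resp, n_chains = 2, n_samples = 3000,
                           n_burn = 1000, seed = 22)
  s <- summary(post)
  est <- function(p) s$mean[s$parameter == p]
  expect_lt(abs(est("w[fm=120,dL=0]") - 0.5), 0.1)
  expect_lt(abs(est("g") - 1), 0.1)
  expect_lt(abs(est("b")), 3)
  expect_true(all(s$rhat < 1.1))
  # kept samples per chain = n_samples - n_burn
  expect_equal(dim(post$draws$g), c(2000, 2))
})

test_that("a generator that ignores the distractor drives w toward one", {
  trials <- make_cell_trials()
  resp <- tibble::tibble(
    index = trials$index,
    response_el = withr::with_seed(23, rnorm(nrow(trials),
                                             trials$target_el, 9)))
  post <- fit_localization(trials, resp, n_chains = 2, n_samples = 3000,
                           n_burn = 1000, seed = 24)
  s <- summary(post)
  expect_gt(s$mean[s$parameter == "w[fm=120,dL=0]"], 0.9)
})

test_that("w is unidentifiable and prior-distributed when target equals distractor", {
  n <- 60
  trials <- tibble::tibble(
    index = 1:(n + 17),
    trial_type = c(rep("double", n), rep("single", 17)),
    target_el = c(rep(30, n), single_sound_locations()),
    distractor_el = c(rep(30, n), rep(NA, 17)),
    fm_hz = c(rep(120, n), rep(NA, 17)),
    delta_l_db = c(rep(0, n), rep(NA, 17)))
  resp <- tibble::tibble(
    index = trials$index,
    response_el = withr::with_seed(25, rnorm(nrow(trials),
                                             trials$target_el, 9)))
  post <- fit_localization(trials, resp, n_chains = 2, n_samples = 4000,
                           n_burn = 1000, seed = 26)
  w <- as.numeric(post$draws[["w[fm=120,dL=0]"]])
  expect_lt(abs(mean(w) - 0.5), 0.05)
  expect_lt(abs(sd(w) - sqrt(1 / 12)), 0.03)
})

test_that("single-predictor regression behaves on perfect, WA, and shuffled data", {
  locs <- rep(single_sound_locations(), 3)
  perfect <- fit_single_predictor(locs, locs, n_chains = 2, seed = 31)
  sp <- summary(perfect)
  expect_lt(abs(sp$mean[sp$parameter == "g"] - 1), 0.01)
  expect_lt(abs(sp$mean[sp$parameter == "b"]), 0.5)

  trials <- make_cell_trials()
  d <- trials$trial_type == "double"
  resp <- simulate_localization(trials, cell_params(w = 0.5, sigma_d = 10),
                                seed = 32)
  pred <- wa_predict(trials$target_el[d], trials$distractor_el[d], 0.5)
  wa_fit <- summary(fit_single_predictor(pred, resp$response_el[d],
                                         n_chains = 2, seed = 33))
  expect_lt(abs(wa_fit$mean[wa_fit$parameter == "g"] - 1), 0.15)

  shuf <- withr::with_seed(34, sample(resp$response_el[d]))
  sh_fit <- summary(fit_single_predictor(pred, shuf, n_chains = 2, seed = 35))
  expect_lt(sh_fit$hdi_lo[sh_fit$parameter == "g"], 0)
  expect_gt(sh_fit$hdi_hi[sh_fit$parameter == "g"], 0)

  expect_error(fit_single_predictor(1:2, 1:2), "at least 3")
  expect_error(fit_single_predictor(1:5, 1:4), "lengths differ")
})

test_that("the Gibbs sampler matches an independent JAGS fit", {
  trials <- make_cell_trials()
  resp <- simulate_localization(
    trials, cell_params(w = 0.7, g = 0.9, b = 2, sigma_s = 8, sigma_d = 10),
    seed = 41)
  mine <- summary(fit_localization(trials, resp, n_chains = 2,
                                   n_samples = 4000, n_burn = 1000,
                                   seed = 42))
  d <- trials$trial_type == "double"
  model <- "model {
    for (i in 1:ns) { Rs[i] ~ dnorm(g * Ts[i] + b, 1 / (sigs * sigs)) }
    for (j in 1:nd) {
      Rd[j] ~ dnorm(g * (w * Td[j] + (1 - w) * Dd[j]) + b,
                    1 / (sigd * sigd))
    }
    g ~ dnorm(1, 0.01); b ~ dnorm(0, 0.01)
    sigs ~ dgamma(1, 0.04); sigd ~ dgamma(1, 0.04); w ~ dbeta(1, 1)
  }"
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(Rs = resp$response_el[!d], Ts = trials$target_el[!d],
                ns = sum(!d), Rd = resp$response_el[d],
                Td = trials$target_el[d], Dd = trials$distractor_el[d],
                nd = sum(d)),
    n.chains = 2, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 43))
  update(jm, 2000, progress.bar = "none")
  sam <- rjags::coda.samples(jm, c("g", "b", "sigs", "sigd", "w"), 4000,
                             progress.bar = "none")
  js <- summary(sam)$statistics
  pick <- function(p) mine$mean[mine$parameter == p]
  expect_equal(pick("g"), unname(js["g", "Mean"]), tolerance = 0.02)
  expect_equal(pick("b"), unname(js["b", "Mean"]), tolerance = 0.5)
  expect_equal(pick("w[fm=120,dL=0]"), unname(js["w", "Mean"]),
               tolerance = 0.02)
  expect_equal(pick("sigma_s"), unname(js["sigs", "Mean"]), tolerance = 0.4)
  expect_equal(pick("sigma_d[fm=120,dL=0]"), unname(js["sigd", "Mean"]),
               tolerance = 0.4)
})

test_that("fitting the WA model to bistable data inflates the double-sound SD", {
  n <- 1000
  trials <- tibble::tibble(
    index = 1:(n + 17),
    trial_type = c(rep("double", n), rep("single", 17)),
    target_el = c(rep(c(30, -30), n / 2), single_sound_locations()),
    distractor_el = c(rep(c(-30, 30), n / 2), rep(NA, 17)),
    fm_hz = c(rep(120, n), rep(NA, 17)),
    delta_l_db = c(rep(0, n), rep(NA, 17)))
  pars <- cell_params(w = 0.5, g = 1, b = 0, sigma_s = 9, sigma_d = 9)
  pars$p_target <- 0.5
  r_wa <- simulate_localization(trials, pars, seed = 51)
  r_bi <- simulate_bistable(trials, pars, seed = 52)
  f <- function(r, s) summary(fit_localization(trials, r, n_chains = 2,
                                               n_samples = 2000,
                                               n_burn = 1000, seed = s))
  s_wa <- f(r_wa, 53)
  s_bi <- f(r_bi, 54)
  sig <- function(s) s$mean[s$parameter == "sigma_d[fm=120,dL=0]"]
  expect_gt(sig(s_bi), sig(s_wa))
})

test_that("pooling concatenates samples across subjects", {
  a <- make_posterior(list(g = withr::with_seed(61, rnorm(2000, 0, 0.1)),
                           b = rnorm(2000)))
  b <- make_posterior(list(g = withr::with_seed(62, rnorm(2000, 10, 0.1)),
                           b = rnorm(2000)))
  one <- pool_posteriors(list(a))
  expect_equal(as.numeric(one$draws$g), as.numeric(a$draws$g))
  pooled <- pool_posteriors(list(a, b))
  expect_equal(mean(pooled$draws$g),
               mean(c(mean(a$draws$g), mean(b$draws$g))), tolerance = 1e-9)
  h <- hdi(as.numeric(pooled$draws$g))
  expect_lt(h[1], 0.3)
  expect_gt(h[2], 9.7)
  bad <- make_posterior(list(gain = rnorm(100)))
  expect_error(pool_posteriors(list(a, bad)), "mismatched")
})

test_that("the weighted-average model nests the single-sound model at w = 1", {
  t_el <- seq(-45, 75, by = 5)
  d_el <- withr::with_seed(63, runif(length(t_el), -45, 75))
  expect_identical(wa_predict(t_el, d_el, w = 1, g = 0.87, b = -1.2),
                   single_predict(t_el, g = 0.87, b = -1.2))
})

test_that("the weight posterior is insensitive to the Gamma hyperparameters", {
  trials <- make_cell_trials()
  resp <- simulate_localization(
    trials, cell_params(w = 0.5, g = 1, b = 0, sigma_s = 8, sigma_d = 10),
    seed = 91)
  w_mean <- function(shape, rate) {
    spec <- localization_model_spec(prior_sigma = c(shape, rate))
    s <- summary(fit_localization(trials, resp, spec = spec, n_chains = 2,
                                  n_samples = 3000, n_burn = 1000,
                                  seed = 92))
    s$mean[s$parameter == "w[fm=120,dL=0]"]
  }
  base <- w_mean(1, 0.04)
  expect_lt(abs(w_mean(0.5, 0.02) - base), 0.02)
  expect_lt(abs(w_mean(2, 0.08) - base), 0.02)
})

test_that("fit input validation catches bad responses and empty cells", {
  trials <- make_cell_trials()
  resp <- tibble::tibble(index = trials$index,
                         response_el = rep(NA_real_, nrow(trials)))
  expect_error(fit_localization(trials, resp), "non-finite")
  one_cell <- trials[c(1, 66), ]  # a condition with a single double trial
  resp2 <- tibble::tibble(index = one_cell$index, response_el = c(1, 2))
  expect_error(fit_localization(one_cell, resp2), "cell")
})
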