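# independently coded direct-formula WAIC, kept deliberately naive
waic_bruteforce <- function(ll) {
  S <- nrow(ll); N <- ncol(ll)
  lppd <- p <- numeric(N)
  for (n in seq_len(N)) {
    lppd[n] <- log(mean(exp(ll[, n])))
    p[n] <- var(ll[, n])
  }
  list(score = -2 * (sum(lppd) - sum(p)), lppd = sum(lppd), p = sum(p),
       se = sqrt(N * var(-2 * (lppd - p))))
}

test_that("waic matches a direct-formula oracle to 1e-10", {
  set.seed(99)
  ll <- matrix(rnorm(50 * 20, -1, 0.5), 50, 20)
  w <- waic(ll)
  bf <- waic_bruteforce(ll)
  expect_equal(w$score, bf$score, tolerance = 1e-10)
  expect_equal(w$lppd, bf$lppd, tolerance = 1e-10)
  expect_equal(w$p_eff, bf$p, tolerance = 1e-10)
  expect_equal(w$se, bf$se, tolerance = 1e-10)
})

test_that("waic handles degenerate and additive cases exactly", {
  # identical rows: no posterior variance, p_waic = 0
  row <- rnorm(10, -2)
  ll <- matrix(row, 30, 10, byrow = TRUE)
  w <- waic(ll)
  expect_equal(w$p_eff, 0)
  expect_equal(w$score, -2 * sum(row))
  # appending a duplicate observation adds its contribution exactly
  set.seed(7)
  ll2 <- matrix(rnorm(40 * 6, -1), 40, 6)
  w6 <- waic(ll2)
  w7 <- waic(cbind(ll2, ll2[, 3]))
  expect_equal(w7$lppd - w6$lppd, w6$pointwise$lppd[3], tolerance = 1e-12)
  expect_equal(w7$p_eff - w6$p_eff, w6$pointwise$p_waic[3], tolerance = 1e-12)
  expect_error(waic(matrix(rnorm(5), 1, 5)), "at least 2 draws")
  expect_error(waic(matrix(c(NA, 1, 2, 3), 2, 2)), "non-finite")
})

test_that("generalized Pareto tail fits recover known shapes", {
  set.seed(123)
  # heavy tail, k = 0.5
  u <- runif(10000)
  x <- ((1 - u)^(-0.5) - 1) / 0.5
  gp <- fit_gpd_tail(x)
  expect_equal(unname(gp["k"]), 0.5, tolerance = 0.05)
  expect_equal(unname(gp["sigma"]), 1, tolerance = 0.1)
  # exponential tail, k = 0
  e <- rexp(10000)
  gp0 <- fit_gpd_tail(e)
  expect_equal(unname(gp0["k"]), 0, tolerance = 0.05)
  # preconditions
  expect_error(fit_gpd_tail(c(1, 2, 3)), "at least 5")
  expect_error(fit_gpd_tail(rep(2, 50)), "degenerate")
  expect_error(fit_gpd_tail(c(-1, 1, 2, 3, 4)), "positive")
})

test_that("psis_loo reduces to the plain average for uniform weights", {
  row <- rnorm(12, -1.5)
  ll <- matrix(row, 200, 12, byrow = TRUE)
  expect_warning(l <- psis_loo(ll), "zero-variance")
  expect_equal(l$elpd, sum(row))
  expect_equal(l$score, -2 * sum(row))
  expect_true(all(is.nan(l$pareto_k)))
})

test_that("psis_loo matches the reference smoothing implementation to 1e-6", {
  # expected values computed once with the reference Python implementation
  # (arviz 0.23.4 _psislw / _gpdfit) on this exact matrix
  set.seed(2024)
  ll <- matrix(rnorm(1000 * 10, mean = -1.2, sd = 0.8), 1000, 10)
  l <- psis_loo(ll)
  expect_equal(l$elpd, -15.237169755595515, tolerance = 1e-6)
  k_ref <- c(0.16835654, 0.17094291, 0.26539732, 0.30502597, 0.45485845,
             0.26309933, 0.27843734, 0.26065490, 0.15792008, 0.05681810)
  expect_equal(unname(l$pareto_k), k_ref, tolerance = 1e-6)
  w <- waic(ll)
  expect_equal(w$score, 30.485058569359524, tolerance = 1e-8)
  # leave-one-out is never better than in-sample
  expect_true(all(l$pointwise$elpd <= l$pointwise$lppd + 1e-10))
})

test_that("scores are invariant to draw order and equivariant in observations", {
  set.seed(31)
  ll <- matrix(rnorm(400 * 8, -1), 400, 8)
  perm <- sample(400)
  expect_equal(waic(ll)$score, waic(ll[perm, ])$score, tolerance = 1e-12)
  l1 <- psis_loo(ll); l2 <- psis_loo(ll[perm, ])
  expect_equal(l1$elpd, l2$elpd, tolerance = 1e-12)
  cperm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  expect_equal(waic(ll[, cperm])$pointwise$lppd, waic(ll)$pointwise$lppd[cperm],
               tolerance = 1e-12)
  expect_equal(psis_loo(ll[, cperm])$pointwise$elpd,
               l1$pointwise$elpd[cperm], tolerance = 1e-12)
})

test_that("both criteria approach the analytic elpd on a conjugate example", {
  # y_i ~ Normal(mu, 1), mu ~ Normal(0, 10^2): posterior and predictive
  # are Gaussian, so the expected log predictive density is closed-form
  set.seed(55)
  n <- 40
  y <- rnorm(n, 0.3, 1)
  tau2 <- 100
  post_var <- 1 / (n + 1 / tau2)
  post_mean <- post_var * sum(y)
  S <- 10000
  mu_draws <- rnorm(S, post_mean, sqrt(post_var))
  ll <- vapply(seq_len(n),
               function(i) dnorm(y[i], mu_draws, 1, log = TRUE),
               numeric(S))
  pred_var <- 1 + post_var
  lpd <- sum(dnorm(y, post_mean, sqrt(pred_var), log = TRUE))
  w <- waic(ll); l <- psis_loo(ll)
  # in-sample lppd equals the analytic log predictive within MC error
  expect_equal(w$lppd, lpd, tolerance = 3 * w$se / 2)
  # exact leave-one-out predictive density is closed-form here
  loo_var <- 1 / ((n - 1) + 1 / tau2)
  loo_mean <- loo_var * (sum(y) - y)
  elpd_exact <- sum(dnorm(y, loo_mean, sqrt(1 + loo_var), log = TRUE))
  expect_equal(l$elpd, elpd_exact, tolerance = 0.15)
  expect_equal(w$elpd, elpd_exact, tolerance = 0.15)
  # effective parameter count is about 1 (a single mean)
  expect_equal(w$p_eff, 1, tolerance = 0.3)
  expect_equal(l$p_eff, 1, tolerance = 0.3)
  expect_equal(w$elpd, l$elpd, tolerance = 0.2)
})

test_that("model comparison ranks, tie-breaks, and validates inputs", {
  mk <- function(score, n = 5) {
    structure(list(criterion = "waic", lppd = 0, p_eff = 0, elpd = -score / 2,
                   score = score, se = 1, pointwise = NULL, pareto_k = NULL,
                   n_draws = 100, n_obs = n), class = "mdnrm_fitscore")
  }
  pair <- function(w, l, n = 5) list(waic = mk(w, n), loo = mk(l, n))
  cmp <- compare_models(list(b = pair(10, 12), a = pair(10, 12), c = pair(5, 20)))
  expect_equal(cmp$model, c("c", "a", "b"))  # ties broken by label
  expect_equal(attr(cmp, "best_waic"), "c")
  expect_equal(attr(cmp, "best_loo"), "a")   # best by LOO differs
  cmp2 <- compare_models(list(x = pair(3, 3), y = pair(-Inf, 1)))
  expect_equal(cmp2$model[1], "y")
  expect_error(compare_models(list(a = pair(1, 1))), "at least 2")
  expect_error(compare_models(list(a = pair(1, 1), b = pair(1, 1, n = 7))),
               "different numbers")
  expect_error(compare_models(list(pair(1, 1), pair(2, 2))), "named")
})

test_that("comparison tables export to CSV and JSON", {
  sim <- small_sim(n_raters = 2, n_cases = 10, seed = 3)
  cfg <- mcmc_config(n_chains = 2, n_warmup = 150, n_samples = 200, seed = 2)
  f1 <- fit_mdnrm(mdnrm_spec("mdnrm_orig"), sim$table, cfg)
  f2 <- fit_mdnrm(mdnrm_spec("mdnrm_r", "gamma"), sim$table, cfg)
  cmp <- suppressWarnings(compare_models(list(orig = f1, r_gamma = f2)))
  expect_equal(nrow(cmp), 2)
  dir <- withr::local_tempdir()
  write_comparison(cmp, file.path(dir, "cmp.csv"), file.path(dir, "cmp.json"))
  back <- read.csv(file.path(dir, "cmp.csv"))
  expect_equal(back$model, cmp$model)
  expect_equal(back$waic, cmp$waic, tolerance = 1e-9)
  js <- jsonlite::read_json(file.path(dir, "cmp.json"))
  expect_equal(js$best_waic, attr(cmp, "best_waic"))
})
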