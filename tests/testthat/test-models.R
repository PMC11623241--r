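test_that("model specs enforce the variant/prior pairing", {
  expect_s3_class(mdnrm_spec("mdnrm_r", "half_normal"), "mdnrm_spec")
  # variants without discrimination take no alpha prior, and vice versa
  expect_error(mdnrm_spec("mdnrm_orig", "gamma"), "no discrimination")
  expect_error(mdnrm_spec("nrm_1pl", "half_normal"), "no discrimination")
  expect_error(mdnrm_spec("mdnrm_r", "none"), "choose alpha_prior")
  expect_equal(mdnrm_spec("mdnrm_orig")$alpha_prior, "none")
  expect_error(mdnrm_spec("mdnrm_r", n_classes = 1), "n_classes")

  shp <- param_shapes(mdnrm_spec("mdnrm_a"), n_cases = 150, n_raters = 6)
  expect_equal(shp, list(theta = c(6, 3, 3), alpha = c(150, 3), beta = 3))
  shp2 <- param_shapes(mdnrm_spec("nrm_2pl", "gamma"), 150, 6)
  expect_equal(shp2, list(theta = 6, alpha = c(150, 3), beta = c(150, 3)))
})

test_that("param_set rejects mis-shaped or out-of-support arrays", {
  spec <- mdnrm_spec("mdnrm_r", "gamma")
  th <- array(0, c(2, 3, 3)); ab <- matrix(1, 4, 3)
  expect_s3_class(param_set(spec, 4, th, ab, ab), "mdnrm_params")
  expect_error(param_set(spec, 4, th, matrix(1, 3, 3), ab), "alpha has shape")
  expect_error(param_set(spec, 4, th, ab, matrix(1, 4, 2)), "beta has shape")
  expect_error(param_set(spec, 4, th, -ab, ab), "nonnegative")
  expect_error(param_set(mdnrm_spec("mdnrm_orig"), 4, th, ab, ab),
               "no alpha")
  expect_error(param_set(spec, 4, th, NULL, ab), "alpha is required")
})

test_that("logits follow each variant's linear predictor", {
  # original MDNRM: z_t = theta_jst + beta_is
  spec <- mdnrm_spec("mdnrm_orig")
  th <- array(0, c(1, 3, 3)); th[1, 1, ] <- c(0, 1, 2)
  be <- matrix(5, 1, 3)
  p <- param_set(spec, 1, th, NULL, be)
  expect_equal(mdnrm_logits(spec, p, 0, 0, 0), c(5, 6, 7))

  # subtype a: z_t = alpha_is * theta_jst + beta_s
  spec_a <- mdnrm_spec("mdnrm_a", "gamma")
  th[1, 1, ] <- c(1, 0, -1)
  pa <- param_set(spec_a, 1, th, matrix(2, 1, 3), rep(0, 3))
  expect_equal(mdnrm_logits(spec_a, pa, 0, 0, 0), c(2, 0, -2))

  # subtype r with all theta zero: logits reduce to the constant beta_is
  spec_r <- mdnrm_spec("mdnrm_r", "gamma")
  be_r <- matrix(seq_len(6) / 10, 2, 3)
  pr <- param_set(spec_r, 2, array(0, c(2, 3, 3)), matrix(1, 2, 3), be_r)
  for (s in 0:2)
    expect_equal(mdnrm_logits(spec_r, pr, 1, 0, s), rep(be_r[2, s + 1], 3))

  expect_error(mdnrm_logits(spec, p, 5, 0, 0), "case index")
  expect_error(mdnrm_logits(spec, p, 0, 3, 0), "rater index")
  expect_error(mdnrm_logits(spec, p, 0, 0, 7), "truth class")
})

test_that("softmax probabilities are exact, positive, and shift-invariant", {
  expect_equal(class_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(class_probabilities(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  set.seed(4)
  for (i in 1:20) {
    z <- rnorm(4, sd = 5)
    p <- class_probabilities(z)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
    expect_equal(class_probabilities(z + rnorm(1, sd = 50)), p,
                 tolerance = 1e-12)
  }
  # large logits stay finite thanks to max subtraction
  expect_equal(sum(class_probabilities(c(1e4, 1e4 - 1, 0))), 1)
  expect_error(class_probabilities(c(Inf, 0)), "finite")
})

test_that("pointwise log-likelihood matches hand enumeration and the uniform case", {
  tbl <- tiny_table()
  # all-zero parameters: every response has probability 1/C
  spec <- mdnrm_spec("mdnrm_r", "gamma")
  p0 <- param_set(spec, 2, array(0, c(2, 3, 3)), matrix(1, 2, 3),
                  matrix(0, 2, 3))
  expect_equal(pointwise_loglik(spec, p0, tbl), rep(log(1 / 3), 4))

  # manual softmax enumeration on a 3-row toy table
  toy <- response_table(data.frame(case = c(0, 0, 1), rater = c(0, 1, 0),
                                   truth = c(1, 1, 0), response = c(2, 1, 0)))
  spec_o <- mdnrm_spec("mdnrm_orig")
  th <- array(seq(-0.8, 0.9, length.out = 18), c(2, 3, 3))
  be <- matrix(seq(-1, 1, length.out = 6), 2, 3)
  pp <- param_set(spec_o, 2, th, NULL, be)
  manual <- numeric(3)
  rows <- data.frame(i = c(0, 0, 1), j = c(0, 1, 0), s = c(1, 1, 0),
                     r = c(2, 1, 0))
  for (n in 1:3) {
    z <- vapply(0:2, function(t) th[rows$j[n] + 1, rows$s[n] + 1, t + 1] +
                  be[rows$i[n] + 1, rows$s[n] + 1], numeric(1))
    manual[n] <- log(exp(z[rows$r[n] + 1]) / sum(exp(z)))
  }
  expect_equal(pointwise_loglik(spec_o, pp, toy), manual, tolerance = 1e-12)
})

test_that("easiness cancels bit-exactly from every MDNRM likelihood", {
  sim <- small_sim(n_raters = 3, n_cases = 15, seed = 3)
  tbl <- sim$table
  for (variant in all_mdnrm_variants) {
    prior <- if (variant == "mdnrm_orig") NULL else "gamma"
    spec <- mdnrm_spec(variant, prior)
    for (rep in 1:5) {
      params <- random_params(spec, 15, 3, seed = 100 + rep)
      ll <- pointwise_loglik(spec, params, tbl)
      shifted <- params
      set.seed(rep)
      pert <- params$beta + rnorm(length(params$beta), sd = 10)
      shifted$beta <- if (is.matrix(params$beta))
        matrix(pert, nrow(params$beta)) else pert
      expect_equal(pointwise_loglik(spec, shifted, tbl), ll,
                   tolerance = 1e-12)
    }
  }
  # but NRM easiness is indexed by response class and does not cancel
  spec2 <- mdnrm_spec("nrm_2pl", "gamma")
  params2 <- random_params(spec2, 15, 3, seed = 2)
  ll2 <- pointwise_loglik(spec2, params2, tbl)
  params2$beta <- params2$beta + matrix(rnorm(45), 15, 3)
  expect_false(isTRUE(all.equal(pointwise_loglik(spec2, params2, tbl), ll2)))
})

test_that("ability raises its class probability; 2PL reduces to 1PL at alpha = 1", {
  spec <- mdnrm_spec("mdnrm_r", "gamma")
  params <- random_params(spec, 10, 2, seed = 9)
  z0 <- mdnrm_logits(spec, params, 3, 1, 2)
  p_before <- class_probabilities(z0)
  params2 <- params
  params2$theta[2, 3, 1] <- params2$theta[2, 3, 1] + 1  # raise theta_jst, t = 0
  p_after <- class_probabilities(mdnrm_logits(spec, params2, 3, 1, 2))
  expect_gt(p_after[1], p_before[1])
  expect_true(all(p_after[-1] < p_before[-1]))

  tbl <- small_sim(n_raters = 2, n_cases = 10, seed = 13)$table
  spec_2pl <- mdnrm_spec("nrm_2pl", "gamma")
  spec_1pl <- mdnrm_spec("nrm_1pl")
  th <- rnorm(2); be <- matrix(rnorm(30), 10, 3)
  p2 <- param_set(spec_2pl, 10, th, matrix(1, 10, 3), be)
  p1 <- param_set(spec_1pl, 10, th, NULL, be)
  expect_equal(pointwise_loglik(spec_2pl, p2, tbl),
               pointwise_loglik(spec_1pl, p1, tbl), tolerance = 1e-14)
})

test_that("log prior sums independent densities with correct support", {
  # all six entries at the mode of Normal(0, 2)
  one <- param_set(mdnrm_spec("mdnrm_orig", n_classes = 2), 1,
                   array(0, c(1, 2, 2)), NULL, matrix(0, 1, 2))
  lp <- log_prior(mdnrm_spec("mdnrm_orig", n_classes = 2), one)
  expect_equal(lp, 6 * dnorm(0, 0, 2, log = TRUE))
  expect_equal(dnorm(0, 0, 2, log = TRUE), log(1 / (2 * sqrt(2 * pi))))

  # alpha outside the support gives -Inf (hand-built list bypasses validation)
  spec_g <- mdnrm_spec("mdnrm_r", "gamma")
  bad <- list(theta = array(0, c(1, 3, 3)), alpha = matrix(-1, 1, 3),
              beta = matrix(0, 1, 3), n_cases = 1L, n_raters = 1L)
  expect_identical(log_prior(spec_g, bad), -Inf)

  # per-entry oracle: independently coded sum over scalar densities
  for (prior in c("gamma", "half_normal")) {
    spec_r <- mdnrm_spec("mdnrm_r", prior)
    params <- random_params(spec_r, 6, 2, seed = 21)
    manual <- 0
    for (x in as.vector(params$theta)) manual <- manual + dnorm(x, 0, 2, log = TRUE)
    for (x in as.vector(params$beta)) manual <- manual + dnorm(x, 0, 2, log = TRUE)
    for (a in as.vector(params$alpha)) {
      manual <- manual + if (prior == "gamma") dgamma(a, 2, rate = 2, log = TRUE)
        else log(2) + dnorm(a, 0, 10, log = TRUE)
    }
    expect_equal(log_prior(spec_r, params), manual, tolerance = 1e-12)
  }
})

test_that("compiled likelihood and gradient agree with the R reference", {
  sim <- small_sim(n_raters = 3, n_cases = 12, seed = 17)
  tbl <- sim$table
  for (variant in c("mdnrm_orig", "mdnrm_a", "mdnrm_b", "mdnrm_r", "nrm_2pl", "nrm_1pl")) {
    prior <- if (variant %in% c("mdnrm_orig", "nrm_1pl")) NULL else "half_normal"
    spec <- mdnrm_spec(variant, prior)
    params <- random_params(spec, 12, 3, seed = 23)
    v <- mdnrm:::params_to_vector(spec, params)
    ll_cpp <- mdnrm:::cpp_loglik_matrix(matrix(v, 1), 12L, 3L, 3L,
                                        mdnrm:::variant_code(variant),
                                        mdnrm:::alpha_prior_code(spec$alpha_prior),
                                        tbl$case, tbl$rater, tbl$truth,
                                        tbl$response, 0L)
    expect_equal(as.vector(ll_cpp), pointwise_loglik(spec, params, tbl),
                 tolerance = 1e-12)
    # joint log density matches R likelihood + prior + log-scale Jacobian
    res <- mdnrm:::cpp_logpost_grad(v, 12L, 3L, 3L,
                                    mdnrm:::variant_code(variant),
                                    mdnrm:::alpha_prior_code(spec$alpha_prior),
                                    tbl$case, tbl$rater, tbl$truth,
                                    tbl$response, 0L)
    jac <- if (is.null(params$alpha)) 0 else sum(log(params$alpha))
    expect_equal(res$lp,
                 sum(pointwise_loglik(spec, params, tbl)) +
                   log_prior(spec, params) + jac, tolerance = 1e-8)
    # central-difference gradient check on a subset of coordinates
    f <- function(vv) mdnrm:::cpp_logpost_grad(
      vv, 12L, 3L, 3L, mdnrm:::variant_code(variant),
      mdnrm:::alpha_prior_code(spec$alpha_prior),
      tbl$case, tbl$rater, tbl$truth, tbl$response, 0L)$lp
    set.seed(31)
    idx <- sample(length(v), 8)
    for (i in idx) {
      h <- 1e-6
      vp <- v; vp[i] <- v[i] + h
      vm <- v; vm[i] <- v[i] - h
      expect_equal(res$grad[i], (f(vp) - f(vm)) / (2 * h), tolerance = 1e-4)
    }
  }
})
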