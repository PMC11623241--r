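VARIANTS <- c("nrm_2pl", "nrm_1pl", "mdnrm_orig", "mdnrm_a", "mdnrm_b", "mdnrm_r")
ALPHA_PRIORS <- c("none", "gamma", "half_normal")
NO_ALPHA_VARIANTS <- c("nrm_1pl", "mdnrm_orig")

variant_code <- function(variant) match(variant, VARIANTS) - 1L
alpha_prior_code <- function(prior) match(prior, ALPHA_PRIORS) - 1L

#' Specify a nominal response model variant
#'
#' The family covers six variants.  Writing i for the case, j for the
#' rater, s for the case's ground-truth class and t for the response
#' class, the logit of response t is
#'
#' \describe{
#'   \item{`nrm_2pl`}{`z_t = alpha_it * theta_j + beta_it` — the
#'     conventional nominal response model with a scalar ability per rater
#'     and per-(case, response-class) discrimination and easiness.}
#'   \item{`nrm_1pl`}{`z_t = theta_j + beta_it` — the one-parameter
#'     reduction without discrimination.}
#'   \item{`mdnrm_orig`}{`z_t = theta_jst + beta_is` — the ability becomes
#'     a (ground truth x response) matrix per rater, conditioned on the
#'     case's true class.}
#'   \item{`mdnrm_a`}{`z_t = alpha_is * theta_jst + beta_s` — adds
#'     per-(case, true-class) discrimination, scalar easiness per class.}
#'   \item{`mdnrm_b`}{`z_t = alpha_s * theta_jst + beta_is` — per-class
#'     discrimination, per-(case, true-class) easiness.}
#'   \item{`mdnrm_r`}{`z_t = alpha_is * theta_jst + beta_is` — both
#'     parameters per (case, true class).}
#' }
#'
#' Class probabilities are the softmax of the logit vector over t.  Note
#' that in all four `mdnrm_*` variants the easiness term does not carry
#' the response index t, so it is constant within the softmax and cancels:
#' the likelihood is invariant to beta, which is therefore informed only
#' by its prior.  This is a property of the model family as defined, and
#' the package preserves it rather than silently re-parameterizing (see
#' the `beta_by_response` escape hatch below).
#'
#' Priors: every theta and beta entry is Normal(0, 2); each discrimination
#' alpha is either Gamma(shape 2, rate 2) (prior mean 1, the conventional
#' discrimination scale) or half-Normal(scale 10).
#'
#' @param variant one of `"nrm_2pl"`, `"nrm_1pl"`, `"mdnrm_orig"`,
#'   `"mdnrm_a"`, `"mdnrm_b"`, `"mdnrm_r"`.
#' @param alpha_prior `"gamma"`, `"half_normal"`, or `"none"`.  Must be
#'   `"none"` exactly for the variants without a discrimination parameter
#'   (`nrm_1pl`, `mdnrm_orig`).
#' @param n_classes number of classes C (>= 2).
#' @param beta_by_response if `TRUE`, index the easiness of the MDNRM
#'   variants by the response class t instead of the ground-truth class s
#'   (`beta_it`, or `beta_t` for `mdnrm_a`), so that it no longer cancels.
#'   Off by default; not part of the canonical model family.
#' @return an object of class `mdnrm_spec`.
#' @examples
#' mdnrm_spec("mdnrm_r", "half_normal", n_classes = 3)
#' @export
mdnrm_spec <- function(variant, alpha_prior = NULL, n_classes = 3,
                       beta_by_response = FALSE) {
  variant <- match.arg(variant, VARIANTS)
  has_alpha <- !(variant %in% NO_ALPHA_VARIANTS)
  if (is.null(alpha_prior)) alpha_prior <- if (has_alpha) "gamma" else "none"
  alpha_prior <- match.arg(alpha_prior, ALPHA_PRIORS)
  if (has_alpha && alpha_prior == "none")
    stop("variant '", variant, "' has a discrimination parameter; ",
         "choose alpha_prior 'gamma' or 'half_normal'", call. = FALSE)
  if (!has_alpha && alpha_prior != "none")
    stop("variant '", variant, "' has no discrimination parameter; ",
         "alpha_prior must be 'none'", call. = FALSE)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  structure(list(variant = variant, alpha_prior = alpha_prior,
                 n_classes = n_classes,
                 theta_prior = c(mean = 0, sd = 2),
                 beta_prior = c(mean = 0, sd = 2),
                 beta_by_response = isTRUE(beta_by_response)),
            class = "mdnrm_spec")
}

#' @export
print.mdnrm_spec <- function(x, ...) {
  cat(sprintf("Model spec: %s, C = %d, alpha prior: %s\n",
              x$variant, x$n_classes, x$alpha_prior))
  if (x$beta_by_response) cat("  (easiness indexed by response class)\n")
  invisible(x)
}

#' Parameter array shapes of a model variant
#'
#' @param spec an [mdnrm_spec()].
#' @param n_cases number of cases I.
#' @param n_raters number of raters J.
#' @return named list with elements `theta`, `alpha`, `beta`; each either a
#'   dimension vector or `NULL` (parameter absent).
#' @export
param_shapes <- function(spec, n_cases, n_raters) {
  I <- as.integer(n_cases); J <- as.integer(n_raters); C <- spec$n_classes
  switch(spec$variant,
    nrm_2pl    = list(theta = J, alpha = c(I, C), beta = c(I, C)),
    nrm_1pl    = list(theta = J, alpha = NULL, beta = c(I, C)),
    mdnrm_orig = list(theta = c(J, C, C), alpha = NULL, beta = c(I, C)),
    mdnrm_a    = list(theta = c(J, C, C), alpha = c(I, C), beta = C),
    mdnrm_b    = list(theta = c(J, C, C), alpha = C, beta = c(I, C)),
    mdnrm_r    = list(theta = c(J, C, C), alpha = c(I, C), beta = c(I, C)))
}

#' Bundle concrete parameter values for a model variant
#'
#' @param spec an [mdnrm_spec()].
#' @param n_cases number of cases I the item parameters refer to.
#' @param theta ability array: `J x C x C` (rater, ground truth, response)
#'   for MDNRM variants, length-J vector for NRM variants.
#' @param alpha discrimination array (shape per [param_shapes()]), or
#'   `NULL` for variants without one.
#' @param beta easiness array (shape per [param_shapes()]).
#' @return object of class `mdnrm_params`.
#' @export
param_set <- function(spec, n_cases, theta, alpha = NULL, beta) {
  J <- if (is.array(theta)) dim(theta)[1] else length(theta)
  shp <- param_shapes(spec, n_cases, J)
  check_shape <- function(x, want, name) {
    if (is.null(want)) {
      if (!is.null(x)) stop("variant '", spec$variant, "' has no ", name,
                            " parameter", call. = FALSE)
      return(NULL)
    }
    if (is.null(x)) stop(name, " is required for variant '", spec$variant,
                         "'", call. = FALSE)
    got <- if (is.array(x)) dim(x) else length(x)
    if (length(got) != length(want) || any(got != want))
      stop(name, " has shape (", paste(got, collapse = ", "),
           "); variant '", spec$variant, "' requires (",
           paste(want, collapse = ", "), ")", call. = FALSE)
    if (!all(is.finite(x))) stop(name, " contains non-finite values", call. = FALSE)
    x
  }
  theta <- check_shape(theta, shp$theta, "theta")
  alpha <- check_shape(alpha, shp$alpha, "alpha")
  beta <- check_shape(beta, shp$beta, "beta")
  if (!is.null(alpha) && any(alpha < 0))
    stop("alpha entries must be nonnegative (prior support)", call. = FALSE)
  structure(list(theta = theta, alpha = alpha, beta = beta,
                 n_cases = as.integer(n_cases), n_raters = as.integer(J)),
            class = "mdnrm_params")
}

#' Softmax class probabilities from a logit vector
#'
#' `p_t = exp(z_t) / sum_h exp(z_h)`, computed with max subtraction for
#' numerical stability.  The output is shift-invariant: adding a constant
#' to every logit leaves it unchanged.
#'
#' @param z numeric vector of logits, one per class.
#' @return probability vector of the same length; strictly positive, sums
#'   to 1.
#' @examples
#' class_probabilities(c(log(2), 0, 0))  # 0.5, 0.25, 0.25
#' @export
class_probabilities <- function(z) {
  if (!is.numeric(z) || length(z) < 2L)
    stop("z must be a numeric vector of length >= 2", call. = FALSE)
  if (!all(is.finite(z))) stop("logits must be finite", call. = FALSE)
  e <- exp(z - max(z))
  e / sum(e)
}

# logit matrix for a set of (case, rater, truth) triples, rows in order;
# cases/raters/truths are 0-based vectors of equal length
logit_matrix <- function(spec, params, case, rater, truth) {
  C <- spec$n_classes
  I <- params$n_cases
  N <- length(case)
  z <- matrix(0, N, C)
  th <- params$theta
  if (spec$variant %in% c("nrm_2pl", "nrm_1pl")) {
    thj <- th[rater + 1L]
    for (t in seq_len(C)) {
      a <- if (spec$variant == "nrm_2pl") params$alpha[cbind(case + 1L, t)] else 1
      z[, t] <- a * thj + params$beta[cbind(case + 1L, t)]
    }
  } else {
    coef <- switch(spec$variant,
      mdnrm_orig = rep(1, N),
      mdnrm_a = params$alpha[cbind(case + 1L, truth + 1L)],
      mdnrm_b = params$alpha[truth + 1L],
      mdnrm_r = params$alpha[cbind(case + 1L, truth + 1L)])
    for (t in seq_len(C)) {
      b <- if (spec$beta_by_response) {
        if (spec$variant == "mdnrm_a") params$beta[t] else params$beta[cbind(case + 1L, t)]
      } else {
        if (spec$variant == "mdnrm_a") params$beta[truth + 1L]
        else params$beta[cbind(case + 1L, truth + 1L)]
      }
      z[, t] <- coef * th[cbind(rater + 1L, truth + 1L, t)] + b
    }
  }
  z
}

#' Logit vector for one (case, rater, ground-truth) triple
#'
#' Evaluates the variant's linear predictor for each candidate response
#' class t.  For NRM variants (scalar ability) the ground truth does not
#' enter the logit and is ignored.
#'
#' @param spec an [mdnrm_spec()].
#' @param params an [param_set()] shaped for `spec`.
#' @param case,rater,truth 0-based indices.
#' @return numeric vector of length C.
#' @export
mdnrm_logits <- function(spec, params, case, rater, truth) {
  I <- params$n_cases; J <- params$n_raters; C <- spec$n_classes
  stopifnot(length(case) == 1L, length(rater) == 1L, length(truth) == 1L)
  if (case < 0L || case >= I) stop("case index out of range [0, ", I, ")", call. = FALSE)
  if (rater < 0L || rater >= J) stop("rater index out of range [0, ", J, ")", call. = FALSE)
  if (truth < 0L || truth >= C) stop("truth class out of range [0, ", C, ")", call. = FALSE)
  drop(logit_matrix(spec, params, as.integer(case), as.integer(rater),
                    as.integer(truth)))
}

#' Pointwise log-likelihood of a response table
#'
#' Returns `log Pr(response_n | case_n, rater_n, truth_n, params)` for
#' every row of the table, in row order.  This is the quantity summed in
#' the posterior and stored per draw for WAIC / PSIS-LOO.
#'
#' @param spec an [mdnrm_spec()].
#' @param params an [param_set()].
#' @param table a [response_table()].
#' @return numeric vector of length `nrow(table)`.
#' @export
pointwise_loglik <- function(spec, params, table) {
  stopifnot(inherits(table, "response_table"))
  if (n_classes(table) != spec$n_classes)
    stop("table has ", n_classes(table), " classes but spec has ",
         spec$n_classes, call. = FALSE)
  if (n_cases(table) != params$n_cases || n_raters(table) != params$n_raters)
    stop("params are sized for ", params$n_cases, " cases x ",
         params$n_raters, " raters; table has ", n_cases(table), " x ",
         n_raters(table), call. = FALSE)
  z <- logit_matrix(spec, params, table$case, table$rater, table$truth)
  zmax <- apply(z, 1, max)
  lse <- zmax + log(rowSums(exp(z - zmax)))
  z[cbind(seq_len(nrow(z)), table$response + 1L)] - lse
}

#' Joint log prior density of a parameter set
#'
#' Sum of independent log densities on the natural scale: Normal(0, 2) for
#' every theta and beta entry; Gamma(2, 2) or half-Normal(10) for every
#' alpha entry as configured.  Returns `-Inf` if any alpha lies outside
#' its support.
#'
#' @inheritParams pointwise_loglik
#' @return scalar log density.
#' @export
log_prior <- function(spec, params) {
  lp <- sum(dnorm(params$theta, 0, 2, log = TRUE)) +
    sum(dnorm(params$beta, 0, 2, log = TRUE))
  if (!is.null(params$alpha)) {
    a <- as.vector(params$alpha)
    if (any(a < 0)) return(-Inf)
    lp <- lp + switch(spec$alpha_prior,
      gamma = sum(dgamma(a, shape = 2, rate = 2, log = TRUE)),
      half_normal = sum(log(2) + dnorm(a, 0, 10, log = TRUE)),
      none = 0)
  }
  lp
}

# ---- flat parameter vector on the sampler's unconstrained scale ----------
# layout [theta | log(alpha) | beta], each block flattened column-major

params_to_vector <- function(spec, params) {
  v <- as.vector(params$theta)
  if (!is.null(params$alpha)) v <- c(v, log(as.vector(params$alpha)))
  c(v, as.vector(params$beta))
}

vector_to_params <- function(spec, v, n_cases, n_raters) {
  shp <- param_shapes(spec, n_cases, n_raters)
  nt <- prod(shp$theta)
  na <- if (is.null(shp$alpha)) 0L else prod(shp$alpha)
  nb <- prod(shp$beta)
  stopifnot(length(v) == nt + na + nb)
  mk <- function(x, d) if (length(d) > 1L) array(x, dim = d) else x
  theta <- mk(v[seq_len(nt)], shp$theta)
  alpha <- if (na > 0) mk(exp(v[nt + seq_len(na)]), shp$alpha) else NULL
  beta <- mk(v[nt + na + seq_len(nb)], shp$beta)
  param_set(spec, n_cases, theta, alpha, beta)
}

#' Columnar serialization of a parameter set
#'
#' Flattens a parameter set into one row per scalar entry with its 0-based
#' index tuple, the interchange format shared with posterior summary
#' tables (so simulated truth values can be joined onto fit summaries).
#'
#' @param params an [param_set()].
#' @return data.frame with columns `parameter`, `index1`, `index2`,
#'   `index3`, `value` (unused indices are `NA`).
#' @export
param_table <- function(params) {
  one <- function(name, x) {
    if (is.null(x)) return(NULL)
    if (is.array(x) && length(dim(x)) == 3L) {
      idx <- expand.grid(index1 = 0:(dim(x)[1] - 1), index2 = 0:(dim(x)[2] - 1),
                         index3 = 0:(dim(x)[3] - 1))
    } else if (is.array(x) && length(dim(x)) == 2L) {
      idx <- expand.grid(index1 = 0:(dim(x)[1] - 1), index2 = 0:(dim(x)[2] - 1))
      idx$index3 <- NA_integer_
    } else {
      idx <- data.frame(index1 = 0:(length(x) - 1), index2 = NA_integer_,
                        index3 = NA_integer_)
    }
    cbind(parameter = name, idx, value = as.vector(x))
  }
  out <- rbind(one("theta", params$theta), one("alpha", params$alpha),
               one("beta", params$beta))
  rownames(out) <- NULL
  out
}
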