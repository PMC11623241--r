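#' MCMC sampler configuration
#'
#' Defaults follow common practice for this model family on a ~900-row
#' observer study: 8 chains, 1,000 warmup iterations and 8,000 retained
#' draws per chain.  Desk-scale work (tests, recovery experiments) should
#' reduce `n_chains` / `n_samples`; the posterior is cheap to re-run.
#'
#' @param n_chains number of independent chains (>= 1; >= 2 for R-hat).
#' @param n_warmup warmup (adaptation) iterations per chain, discarded.
#' @param n_samples retained draws per chain.
#' @param seed master seed; per-chain seeds are derived deterministically
#'   from it, so identical configurations reproduce bit-identical draws.
#' @param target_accept dual-averaging target acceptance statistic.
#' @param max_depth maximum binary tree depth per trajectory.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 8, n_warmup = 1000, n_samples = 8000,
                        seed = 1, target_accept = 0.8, max_depth = 10) {
  stopifnot(n_chains >= 1, n_warmup >= 1, n_samples >= 1,
            target_accept > 0, target_accept < 1, max_depth >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 n_warmup = as.integer(n_warmup),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed),
                 target_accept = target_accept,
                 max_depth = as.integer(max_depth)),
            class = "mcmc_config")
}

# derive a per-chain seed; kept below 2^31 for R's set.seed
chain_seed <- function(master, chain)
  (abs(master) * 100003 + 7919 * chain) %% 2147483629

# draw one chain initialization from the prior
prior_init <- function(spec, n_cases, n_raters, seed) {
  shp <- param_shapes(spec, n_cases, n_raters)
  nt <- prod(shp$theta)
  na <- if (is.null(shp$alpha)) 0L else prod(shp$alpha)
  nb <- prod(shp$beta)
  with_local_seed(seed, {
    theta <- rnorm(nt, 0, 2)
    u <- if (na > 0) {
      a <- switch(spec$alpha_prior,
                  gamma = rgamma(na, shape = 2, rate = 2),
                  half_normal = abs(rnorm(na, 0, 10)))
      log(pmax(a, 1e-6))
    } else numeric(0)
    beta <- rnorm(nb, 0, 2)
    c(theta, u, beta)
  })
}

#' Fit a nominal response model by MCMC
#'
#' Samples the joint posterior of all model parameters with a built-in
#' No-U-Turn sampler (dual-averaging step size, diagonal mass matrix
#' adapted during warmup).  Discrimination parameters are sampled on the
#' log scale with the Jacobian folded into the target, so their draws
#' respect the positive prior support exactly.  Chains are initialized
#' independently from the prior and run sequentially; the whole fit is a
#' deterministic function of `config`.
#'
#' Divergent transitions after warmup are counted per chain and reported,
#' never dropped.
#'
#' @param spec an [mdnrm_spec()].
#' @param table a [response_table()]; its number of classes must match
#'   `spec`.
#' @param config an [mcmc_config()].
#' @param likelihood if `FALSE`, sample from the prior only (the
#'   likelihood term is switched off); used for prior-predictive checks.
#' @return An object of class `mdnrm_fit` with elements:
#'   \describe{
#'     \item{draws}{named list of arrays indexed (chain, draw, index...):
#'       `theta` (J or J x C x C), `alpha` (natural scale; absent for
#'       variants without discrimination), `beta`.}
#'     \item{loglik}{S x N matrix of pointwise log-likelihood at every
#'       retained draw, chains stacked in order (S = chains x draws).}
#'     \item{spec, config}{the inputs.}
#'     \item{sampler}{per-chain step sizes, divergence counts, mean
#'       acceptance statistic, tree-depth saturation counts.}
#'   }
#' @export
fit_mdnrm <- function(spec, table, config = mcmc_config(), likelihood = TRUE) {
  stopifnot(inherits(spec, "mdnrm_spec"), inherits(table, "response_table"),
            inherits(config, "mcmc_config"))
  if (n_classes(table) != spec$n_classes)
    stop("table has ", n_classes(table), " classes but spec has ",
         spec$n_classes, call. = FALSE)
  I <- n_cases(table); J <- n_raters(table); C <- spec$n_classes
  shp <- param_shapes(spec, I, J)
  vcode <- variant_code(spec$variant)
  pcode <- alpha_prior_code(spec$alpha_prior)
  bresp <- as.integer(spec$beta_by_response)

  t0 <- proc.time()[["elapsed"]]
  chains <- vector("list", config$n_chains)
  diag_rows <- vector("list", config$n_chains)
  for (k in seq_len(config$n_chains)) {
    sk <- chain_seed(config$seed, k)
    init <- prior_init(spec, I, J, sk)
    res <- cpp_nuts_chain(init, I, J, C, vcode, pcode,
                          table$case, table$rater, table$truth, table$response,
                          config$n_warmup, config$n_samples, sk,
                          config$target_accept, config$max_depth,
                          likelihood, bresp)
    chains[[k]] <- res$draws
    diag_rows[[k]] <- data.frame(chain = k, step_size = res$step_size,
                                 divergences = res$divergences,
                                 max_depth_hits = res$max_depth_hits,
                                 accept_mean = res$accept_mean,
                                 n_grad = res$n_grad)
  }
  sampler <- do.call(rbind, diag_rows)

  nt <- prod(shp$theta)
  na <- if (is.null(shp$alpha)) 0L else prod(shp$alpha)
  nb <- prod(shp$beta)
  K <- config$n_chains; S <- config$n_samples

  block_array <- function(cols, dims, transform = identity) {
    flat <- array(NA_real_, dim = c(K, S, length(cols)))
    for (k in seq_len(K)) flat[k, , ] <- transform(chains[[k]][, cols, drop = FALSE])
    dim(flat) <- c(K, S, dims)
    flat
  }
  draws <- list(theta = block_array(seq_len(nt), shp$theta))
  if (na > 0) draws$alpha <- block_array(nt + seq_len(na), shp$alpha, exp)
  draws$beta <- block_array(nt + na + seq_len(nb), shp$beta)

  pooled <- do.call(rbind, chains)
  loglik <- cpp_loglik_matrix(pooled, I, J, C, vcode, pcode,
                              table$case, table$rater, table$truth,
                              table$response, bresp)

  structure(list(draws = draws, loglik = loglik, spec = spec, config = config,
                 table = table,
                 dims = list(I = I, J = J, C = C, N = nrow(table)),
                 sampler = sampler,
                 likelihood = likelihood,
                 elapsed = proc.time()[["elapsed"]] - t0),
            class = "mdnrm_fit")
}

#' @export
print.mdnrm_fit <- function(x, ...) {
  cat(sprintf("MDNRM fit: %s (alpha prior: %s)\n", x$spec$variant,
              x$spec$alpha_prior))
  cat(sprintf("  data: %d cases x %d raters x %d classes (%d responses)\n",
              x$dims$I, x$dims$J, x$dims$C, x$dims$N))
  cat(sprintf("  %d chains x %d draws (warmup %d), %.1f s\n",
              x$config$n_chains, x$config$n_samples, x$config$n_warmup,
              x$elapsed))
  dv <- sum(x$sampler$divergences)
  cat(sprintf("  divergent transitions after warmup: %d\n", dv))
  invisible(x)
}

# draws for one scalar parameter as an (iterations x chains) matrix
param_draws_matrix <- function(fit, family, index = NULL) {
  arr <- fit$draws[[family]]
  if (is.null(arr)) stop("no parameter family '", family, "' in this fit",
                         call. = FALSE)
  nd <- length(dim(arr)) - 2L
  if (nd == 0L) return(t(arr))
  if (is.null(index) || length(index) != nd)
    stop("family '", family, "' needs a 0-based index of length ", nd,
         call. = FALSE)
  idx <- as.integer(index) + 1L
  extent <- dim(arr)[-(1:2)]
  if (any(idx < 1L) || any(idx > extent))
    stop("index (", paste(index, collapse = ","), ") out of range for '",
         family, "'", call. = FALSE)
  m <- do.call(`[`, c(list(arr, TRUE, TRUE), as.list(idx)))
  t(m)  # (chains x draws) -> (draws x chains)
}

# pooled draws vector for one scalar parameter (chains concatenated)
param_draws <- function(fit, family, index = NULL) {
  as.vector(param_draws_matrix(fit, family, index))
}

#' Split R-hat convergence diagnostic
#'
#' Computes the split-chain potential scale reduction factor.  The default
#' `"rank"` method rank-normalizes the draws first and returns the larger
#' of the bulk diagnostic and the diagnostic of the median-folded draws,
#' which is sensitive to both location and scale disagreement between
#' chains.  `"split"` is the plain split R-hat on the raw draws.
#'
#' Values near 1 indicate the chains are mixing over the same
#' distribution; the conventional acceptance threshold for this model
#' family is 1.10.
#'
#' @param x draws: an (iterations x chains) matrix, or an [fit_mdnrm()]
#'   object (then give `family` and `index`).
#' @param ... passed between methods.
#' @return scalar R-hat (>= ~1), or `NaN` with a warning for zero-variance
#'   draws.
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @param method `"rank"` (rank-normalized, folded) or `"split"` (plain).
#' @export
rhat.default <- function(x, method = c("rank", "split"), ...) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("R-hat needs at least 2 chains", call. = FALSE)
  if (nrow(x) < 4L)
    stop("R-hat needs at least 4 draws per chain", call. = FALSE)
  n2 <- floor(nrow(x) / 2)
  m <- cbind(x[seq_len(n2), , drop = FALSE],
             x[n2 + seq_len(n2), , drop = FALSE])
  if (all(m == m[1L])) {
    warning("zero-variance draws; R-hat undefined")
    return(NaN)
  }
  if (method == "split") return(split_rhat_basic(m))
  bulk <- split_rhat_basic(rank_normalize(m))
  folded <- split_rhat_basic(rank_normalize(abs(m - median(m))))
  max(bulk, folded)
}

#' @rdname rhat
#' @param family parameter family name (`"theta"`, `"alpha"`, `"beta"`).
#' @param index 0-based index tuple within the family.
#' @export
rhat.mdnrm_fit <- function(x, family, index = NULL,
                           method = c("rank", "split"), ...) {
  rhat(param_draws_matrix(x, family, index), method = match.arg(method))
}

rank_normalize <- function(m) {
  z <- qnorm((rank(m, ties.method = "average") - 3 / 8) / (length(m) + 1 / 4))
  dim(z) <- dim(m)
  z
}

split_rhat_basic <- function(m) {
  n <- nrow(m)
  w <- mean(apply(m, 2, var))
  b <- n * var(colMeans(m))
  if (!is.finite(w) || w == 0) return(NaN)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Convergence report over every parameter of a fit
#'
#' Applies [rhat()] to each scalar parameter and declares the fit
#' converged when the maximum lies below `threshold` (1.10 by
#' convention for this model family).
#'
#' @param fit an [fit_mdnrm()] object.
#' @param threshold convergence cutoff on R-hat.
#' @inheritParams rhat.default
#' @return list with `max_rhat`, `converged`, `threshold`, and `table`, a
#'   data.frame of every parameter sorted by decreasing R-hat.
#' @export
convergence_report <- function(fit, threshold = 1.10,
                               method = c("rank", "split")) {
  stopifnot(inherits(fit, "mdnrm_fit"))
  method <- match.arg(method)
  rows <- list()
  for (family in names(fit$draws)) {
    arr <- fit$draws[[family]]
    extent <- dim(arr)[-(1:2)]
    if (length(extent) == 0L) {
      idx <- matrix(integer(0), nrow = 1, ncol = 0)
    } else {
      idx <- as.matrix(expand.grid(lapply(extent, function(e) 0:(e - 1L))))
    }
    r <- numeric(nrow(idx))
    nm <- character(nrow(idx))
    for (p in seq_len(nrow(idx))) {
      r[p] <- suppressWarnings(
        rhat(param_draws_matrix(fit, family, idx[p, ]), method = method))
      nm[p] <- if (ncol(idx) > 0)
        sprintf("%s[%s]", family, paste(idx[p, ], collapse = ","))
      else family
    }
    rows[[family]] <- data.frame(parameter = nm, family = family, rhat = r)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab <- tab[order(-tab$rhat), ]
  max_rhat <- suppressWarnings(max(tab$rhat, na.rm = TRUE))
  structure(list(max_rhat = max_rhat,
                 converged = is.finite(max_rhat) && max_rhat < threshold,
                 threshold = threshold, table = tab),
            class = "mdnrm_convergence")
}

#' @export
print.mdnrm_convergence <- function(x, ...) {
  cat(sprintf("max R-hat = %.4f over %d parameters (threshold %.2f): %s\n",
              x$max_rhat, nrow(x$table), x$threshold,
              if (x$converged) "converged" else "NOT converged"))
  print(utils::head(x$table, 5))
  invisible(x)
}

#' Persist or restore a fit
#'
#' `write_fit()` stores the named draw arrays and pointwise log-likelihood
#' in `dir/draws.rds` and a human-readable JSON sidecar
#' (`dir/manifest.json`) describing the model spec, sampler configuration,
#' data dimensions, and sampler diagnostics.  `read_fit()` restores the
#' fit object.
#'
#' @param fit an [fit_mdnrm()] object.
#' @param dir directory to create/use.
#' @return `write_fit()` returns `dir` invisibly; `read_fit()` the fit.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "mdnrm_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(fit, file.path(dir, "draws.rds"))
  sidecar <- list(spec = unclass(fit$spec), config = unclass(fit$config),
                  dims = fit$dims, sampler = fit$sampler,
                  package_version = as.character(packageVersion("mdnrm")),
                  written = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(sidecar, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  f <- file.path(dir, "draws.rds")
  if (!file.exists(f)) stop("no fit found in ", dir, call. = FALSE)
  readRDS(f)
}
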