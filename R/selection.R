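# column-wise log( mean_s exp(ll) ) via max subtraction
col_log_mean_exp <- function(ll) {
  m <- apply(ll, 2, max)
  m + log(colMeans(exp(sweep(ll, 2, m, "-"))))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

as_loglik_matrix <- function(x) {
  if (inherits(x, "mdnrm_fit")) x <- x$loglik
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("log-likelihood matrix has non-finite entries",
                               call. = FALSE)
  x
}

new_fitscore <- function(criterion, lppd, p_eff, elpd, se, pointwise,
                         pareto_k = NULL, S, N) {
  structure(list(criterion = criterion, lppd = lppd, p_eff = p_eff,
                 elpd = elpd, score = -2 * elpd, se = se,
                 pointwise = pointwise, pareto_k = pareto_k,
                 n_draws = S, n_obs = N),
            class = "mdnrm_fitscore")
}

#' @export
print.mdnrm_fitscore <- function(x, ...) {
  cat(sprintf("%s: %.1f +/- %.1f (deviance scale; elpd %.1f, p_eff %.1f, N = %d, S = %d)\n",
              toupper(x$criterion), x$score, x$se, x$elpd, x$p_eff,
              x$n_obs, x$n_draws))
  if (!is.null(x$pareto_k)) {
    nbad <- sum(x$pareto_k > 0.7, na.rm = TRUE)
    cat(sprintf("  Pareto k > 0.7 for %d of %d observations\n", nbad, x$n_obs))
  }
  invisible(x)
}

#' Widely applicable information criterion
#'
#' Computes WAIC from an S x N pointwise log-likelihood matrix (S
#' posterior draws, N observations):
#' `lppd = sum_n log mean_s exp(ll_sn)`,
#' `p_waic = sum_n var_s(ll_sn)` (sample variance, denominator S - 1), and
#' the reported score is on the deviance scale, `-2 (lppd - p_waic)`, so
#' smaller is better.  The standard error is `sqrt(N * var_n)` of the
#' pointwise deviance-scale contributions.
#'
#' @param x an S x N log-likelihood matrix or an [fit_mdnrm()] object
#'   (whose stored `loglik` is used).
#' @return an object of class `mdnrm_fitscore` with elements `lppd`,
#'   `p_eff`, `elpd`, `score`, `se`, and the `pointwise` table.
#' @seealso [psis_loo()], [compare_models()]
#' @export
waic <- function(x) {
  ll <- as_loglik_matrix(x)
  S <- nrow(ll); N <- ncol(ll)
  if (S < 2) stop("need at least 2 draws to estimate p_waic", call. = FALSE)
  lppd_i <- col_log_mean_exp(ll)
  p_i <- apply(ll, 2, var)
  elpd_i <- lppd_i - p_i
  se <- sqrt(N * var(-2 * elpd_i))
  new_fitscore("waic", sum(lppd_i), sum(p_i), sum(elpd_i), se,
               pointwise = data.frame(lppd = lppd_i, p_waic = p_i,
                                      elpd = elpd_i),
               S = S, N = N)
}

#' Generalized Pareto quantile function (shape k, scale sigma)
#' @noRd
qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma / k * ((1 - p)^(-k) - 1)
}

#' Fit a generalized Pareto distribution to threshold excesses
#'
#' Profile-likelihood estimator of the GPD shape (k) and scale (sigma) in
#' the Zhang–Stephens style: the likelihood is profiled over a quantile
#' grid of the transformed parameter, averaged under the implied weights,
#' and (by default) the shape is shrunk toward 0.5 by a weakly informative
#' prior equivalent to 10 observations, as in standard Pareto-smoothing
#' implementations.
#'
#' @param excesses positive excesses over the threshold, any order.
#' @param wip apply the weakly informative shape prior.
#' @return named vector `c(k = shape, sigma = scale)`.
#' @export
fit_gpd_tail <- function(excesses, wip = TRUE) {
  x <- sort(as.numeric(excesses))
  n <- length(x)
  if (n < 5) stop("need at least 5 excesses to fit the tail", call. = FALSE)
  if (any(x <= 0)) stop("excesses must be strictly positive", call. = FALSE)
  if (x[n] - x[1] < .Machine$double.eps * x[n])
    stop("degenerate excesses: all values (nearly) equal", call. = FALSE)
  prior_b <- 3
  prior_k <- 10
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  # quantile grid over the transformed parameter b = -k/sigma
  b <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_b * x[floor(n / 4 + 0.5)])
  k_of <- function(bj) mean(log1p(-bj * x))
  kk <- vapply(b, k_of, numeric(1))
  l_b <- n * (log(-b / kk) - kk - 1)  # profile log likelihood
  l_b[!is.finite(l_b)] <- -Inf
  w <- exp(l_b - max(l_b))
  w <- w / sum(w)
  b_hat <- sum(b * w)
  k <- k_of(b_hat)
  sigma <- -k / b_hat
  if (wip) k <- (k * n + 0.5 * prior_k) / (n + prior_k)
  c(k = k, sigma = sigma)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Approximates exact leave-one-out cross-validation from posterior draws.
#' For each observation the raw importance weights are the reciprocal
#' pointwise likelihoods; the largest `M = min(ceil(0.2 S), ceil(3 sqrt(S)))`
#' log-weights are replaced by expected order statistics of a generalized
#' Pareto distribution fitted to their excesses ([fit_gpd_tail()]),
#' truncated at the raw maximum.  The fitted shape `k` diagnoses
#' reliability; observations with `k > 0.7` are counted and reported.
#'
#' The score is on the deviance scale, `-2 sum_n elpd_loo_n`, with the
#' same standard-error convention as [waic()].
#'
#' @inheritParams waic
#' @param khat_warn shape threshold above which an observation's estimate
#'   is flagged unreliable.
#' @return an `mdnrm_fitscore` including the per-observation `pareto_k`.
#' @export
psis_loo <- function(x, khat_warn = 0.7) {
  ll <- as_loglik_matrix(x)
  S <- nrow(ll); N <- ncol(ll)
  if (S < 2) stop("need at least 2 draws", call. = FALSE)
  M <- min(ceiling(0.2 * S), ceiling(3 * sqrt(S)))
  lppd_i <- col_log_mean_exp(ll)
  elpd_i <- numeric(N)
  k_i <- rep(NaN, N)
  n_degenerate <- 0L
  for (nn in seq_len(N)) {
    lw <- -ll[, nn]
    lw <- lw - max(lw)
    if (max(lw) - min(lw) < 1e-12) {  # uniform weights: plain average
      elpd_i[nn] <- lppd_i[nn]
      n_degenerate <- n_degenerate + 1L
      next
    }
    if (M >= 5) {
      cutoff <- sort(lw, partial = S - M)[S - M]  # (M+1)-th largest
      tail_ids <- which(lw > cutoff)              # ties with cutoff excluded
      nt <- length(tail_ids)
      exc <- exp(lw[tail_ids]) - exp(cutoff)
      if (nt >= 5 && length(unique(exc)) >= 2) {
        gp <- tryCatch(fit_gpd_tail(exc, wip = TRUE), error = function(e) NULL)
        if (is.null(gp)) { elpd_i[nn] <- log_sum_exp(lw + ll[, nn]) - log_sum_exp(lw); next }
        k_i[nn] <- gp[["k"]]
        qs <- qgpd((seq_len(nt) - 0.5) / nt, gp[["k"]], gp[["sigma"]])
        sm <- pmin(log(qs + exp(cutoff)), 0)  # truncate at the raw maximum
        lw[tail_ids[order(lw[tail_ids])]] <- sort(sm)
      }
    }
    elpd_i[nn] <- log_sum_exp(lw + ll[, nn]) - log_sum_exp(lw)
  }
  if (n_degenerate > 0)
    warning(n_degenerate, " observation(s) had zero-variance importance ",
            "weights; their elpd falls back to the in-sample lppd")
  nbad <- sum(k_i > khat_warn, na.rm = TRUE)
  if (nbad > 0)
    warning(nbad, " observation(s) with Pareto k > ", khat_warn,
            "; PSIS-LOO may be unreliable for them")
  se <- sqrt(N * var(-2 * elpd_i))
  new_fitscore("loo", sum(lppd_i), sum(lppd_i - elpd_i), sum(elpd_i), se,
               pointwise = data.frame(lppd = lppd_i, elpd = elpd_i),
               pareto_k = k_i, S = S, N = N)
}

#' Compare fitted models by WAIC and PSIS-LOO
#'
#' Scores each fitted model on both criteria and ranks them (ascending:
#' smaller deviance-scale score is better).  The best model by WAIC and
#' the best by LOO may differ; both labels are reported.
#'
#' @param fits named list of [fit_mdnrm()] objects fitted to the *same*
#'   table, or a named list of lists with elements `waic` and `loo`
#'   (precomputed `mdnrm_fitscore`s).
#' @param sort_by `"waic"` or `"loo"`.
#' @return object of class `mdnrm_comparison`: a data.frame with columns
#'   `model`, `waic`, `waic_se`, `loo`, `loo_se`, sorted by the chosen
#'   criterion with ties broken by label, and attributes `best_waic`,
#'   `best_loo`.
#' @export
compare_models <- function(fits, sort_by = c("waic", "loo")) {
  sort_by <- match.arg(sort_by)
  if (length(fits) < 2) stop("need at least 2 models to compare", call. = FALSE)
  if (is.null(names(fits)) || any(names(fits) == ""))
    stop("fits must be a named list", call. = FALSE)
  scores <- lapply(fits, function(f) {
    if (inherits(f, "mdnrm_fit")) list(waic = waic(f), loo = suppressWarnings(psis_loo(f)))
    else if (is.list(f) && inherits(f$waic, "mdnrm_fitscore") &&
             inherits(f$loo, "mdnrm_fitscore")) f
    else stop("each element must be an mdnrm_fit or a list(waic=, loo=)",
              call. = FALSE)
  })
  n_obs <- vapply(scores, function(s) s$waic$n_obs, numeric(1))
  if (length(unique(n_obs)) != 1)
    stop("models were scored on different numbers of observations",
         call. = FALSE)
  tab <- data.frame(model = names(scores),
                    waic = vapply(scores, function(s) s$waic$score, numeric(1)),
                    waic_se = vapply(scores, function(s) s$waic$se, numeric(1)),
                    loo = vapply(scores, function(s) s$loo$score, numeric(1)),
                    loo_se = vapply(scores, function(s) s$loo$se, numeric(1)))
  tab <- tab[order(tab[[sort_by]], tab$model), ]
  rownames(tab) <- NULL
  structure(tab,
            best_waic = tab$model[which.min(tab$waic)],
            best_loo = tab$model[which.min(tab$loo)],
            sort_by = sort_by,
            class = c("mdnrm_comparison", "data.frame"))
}

#' @export
print.mdnrm_comparison <- function(x, ...) {
  cat("Model comparison (deviance scale, smaller is better):\n")
  df <- as.data.frame(x)
  df$waic <- sprintf("%.1f +/- %.1f", df$waic, df$waic_se)
  df$loo <- sprintf("%.1f +/- %.1f", df$loo, df$loo_se)
  print(df[, c("model", "waic", "loo")], row.names = FALSE)
  cat(sprintf("best by wAIC: %s;  best by LOO: %s\n",
              attr(x, "best_waic"), attr(x, "best_loo")))
  invisible(x)
}

#' Export a model comparison
#'
#' Writes the ranking both as CSV (model, wAIC +/- se, LOO +/- se) and as
#' a machine-readable JSON report with the best-model labels.
#'
#' @param comparison an [compare_models()] result.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisible `NULL`.
#' @export
write_comparison <- function(comparison, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(comparison, "mdnrm_comparison"))
  if (!is.null(csv_path))
    write.csv(as.data.frame(comparison), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(table = as.data.frame(comparison),
           best_waic = attr(comparison, "best_waic"),
           best_loo = attr(comparison, "best_loo")),
      json_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}
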