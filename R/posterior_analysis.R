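#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing a fraction `prob` of the draws:
#' among all windows of `ceil(prob * n)` consecutive sorted draws, the one
#' of minimum width (lowest such window on ties).  For unimodal symmetric
#' posteriors this coincides with the central interval; for skewed ones it
#' is shorter.
#'
#' @param draws numeric sample vector.
#' @param prob interval mass, in (0, 1).  Default 0.94, the conventional
#'   reporting interval for this analysis family.
#' @return named numeric vector `c(lower, upper)`.
#' @examples
#' hdi(rnorm(1e4), 0.94)
#' @export
hdi <- function(draws, prob = 0.94) {
  if (!is.numeric(prob) || length(prob) != 1 || prob <= 0 || prob >= 1)
    stop("prob must lie strictly between 0 and 1", call. = FALSE)
  x <- sort(as.numeric(draws))
  n <- length(x)
  if (n < 1) stop("empty sample", call. = FALSE)
  k <- ceiling(prob * n)
  if (k >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[k:n] - x[seq_len(n - k + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + k - 1])
}

#' Probability of direction
#'
#' The larger of the posterior probabilities that the quantity is positive
#' or negative — an index of how certainly an effect has a sign, ranging
#' from 0.5 (no directional information) to 1 (sign certain).  Draws
#' exactly at zero are split evenly between the two signs.
#'
#' @param draws numeric sample vector (typically of a difference).
#' @return scalar in \[0.5, 1\].
#' @examples
#' pd(rnorm(1e4, mean = 1))  # about pnorm(1) = 0.841
#' @export
pd <- function(draws) {
  x <- as.numeric(draws)
  if (length(x) == 0) stop("empty sample", call. = FALSE)
  pos <- mean(x > 0) + 0.5 * mean(x == 0)
  max(pos, 1 - pos)
}

#' Contrast two ability parameters
#'
#' Forms the pooled-chain posterior of `theta_a - theta_b`, its
#' probability of direction, and its highest density interval.  The
#' contrast is called significant when 0 lies outside the HDI of the
#' difference — the standard HDI existence test; the PD value is always
#' reported alongside so any other threshold can be applied.
#'
#' For MDNRM variants, `a` and `b` are 0-based index triples
#' `c(rater, ground_truth, response)`; e.g. `c(1, 2, 2)` is rater 1's
#' ability to call class 2 when the truth is class 2.  For NRM variants
#' (scalar ability per rater) they are single rater indices.
#'
#' @param fit an [fit_mdnrm()] object.
#' @param a,b parameter indices as above.
#' @param prob HDI mass for the significance call (default 0.94).
#' @return object of class `mdnrm_contrast` with `pd`, `hdi`,
#'   `significant`, and the difference draws.
#' @export
compare_abilities <- function(fit, a, b, prob = 0.94) {
  stopifnot(inherits(fit, "mdnrm_fit"))
  ndim <- length(dim(fit$draws$theta)) - 2L
  if (ndim == 1L) {  # NRM variants: one scalar ability per rater
    if (length(a) != 1L || length(b) != 1L)
      stop("variant '", fit$spec$variant, "' has a scalar ability per rater; ",
           "a and b must be single rater indices", call. = FALSE)
    J <- fit$dims$J
    if (a < 0 || a >= J || b < 0 || b >= J)
      stop("rater index out of range [0, ", J, ")", call. = FALSE)
    da <- as.vector(fit$draws$theta[, , a + 1L])
    db <- as.vector(fit$draws$theta[, , b + 1L])
  } else {
    if (length(a) != 3L || length(b) != 3L)
      stop("MDNRM abilities are indexed (rater, ground_truth, response); ",
           "a and b must be 0-based triples", call. = FALSE)
    da <- param_draws(fit, "theta", a)
    db <- param_draws(fit, "theta", b)
  }
  d <- da - db
  h <- hdi(d, prob)
  structure(list(a = a, b = b, pd = pd(d), hdi = h, prob = prob,
                 significant = h[["lower"]] > 0 || h[["upper"]] < 0,
                 draws_a = da, draws_b = db, diff_draws = d,
                 variant = fit$spec$variant),
            class = "mdnrm_contrast")
}

#' @export
print.mdnrm_contrast <- function(x, ...) {
  fmt_idx <- function(i) paste0("theta[", paste(i, collapse = ","), "]")
  cat(sprintf("Contrast %s - %s (%s):\n", fmt_idx(x$a), fmt_idx(x$b), x$variant))
  cat(sprintf("  mean difference %.3f, PD = %.3f, %d%% HDI [%.3f, %.3f]\n",
              mean(x$diff_draws), x$pd, round(100 * x$prob),
              x$hdi[["lower"]], x$hdi[["upper"]]))
  cat(sprintf("  significant (0 outside HDI): %s\n",
              if (x$significant) "yes" else "no"))
  invisible(x)
}

#' Posterior summary table for one parameter family
#'
#' One row per scalar parameter with posterior mean, sd, HDI bounds, and
#' split R-hat, in the column layout conventional for ability-parameter
#' reports: `rad_index` (rater), `index1` (ground-truth class), `index2`
#' (response class) for MDNRM theta; item/class indices for alpha and
#' beta.  All indices are 0-based.
#'
#' @param fit an [fit_mdnrm()] object.
#' @param family `"theta"`, `"alpha"`, or `"beta"`.
#' @param prob HDI mass (default 0.94, printed as `HDI_3%` / `HDI_97%`).
#' @param rhat_method passed to [rhat()].
#' @return data.frame; HDI column names carry the tail percentages.
#' @export
summary_table <- function(fit, family = "theta", prob = 0.94,
                          rhat_method = "rank") {
  stopifnot(inherits(fit, "mdnrm_fit"))
  arr <- fit$draws[[family]]
  if (is.null(arr)) stop("no parameter family '", family, "' in this fit",
                         call. = FALSE)
  extent <- dim(arr)[-(1:2)]
  nd <- length(extent)
  if (nd == 0L) {
    idx <- matrix(integer(0), nrow = 1, ncol = 0)
  } else {
    # vary the last index fastest, as in conventional report ordering
    grid <- expand.grid(rev(lapply(extent, function(e) 0:(e - 1L))))
    idx <- as.matrix(grid[, rev(seq_len(nd)), drop = FALSE])
  }
  P <- nrow(idx)
  means <- sds <- lo <- hi <- rh <- numeric(P)
  for (p in seq_len(P)) {
    i <- if (nd > 0) idx[p, ] else NULL
    m <- param_draws_matrix(fit, family, i)
    v <- as.vector(m)
    means[p] <- mean(v); sds[p] <- sd(v)
    h <- hdi(v, prob)
    lo[p] <- h[["lower"]]; hi[p] <- h[["upper"]]
    rh[p] <- if (ncol(m) >= 2)
      suppressWarnings(rhat(m, method = rhat_method)) else NA_real_
  }
  idx_names <- if (family == "theta" && nd == 3L) {
    c("rad_index", "index1", "index2")
  } else if (nd > 0) {
    c("item_index", "index1", "index2")[seq_len(nd) + (nd == 1L)]
  } else character(0)
  out <- data.frame(matrix(idx, nrow = P))
  names(out) <- idx_names
  tails <- round(c((1 - prob) / 2, 1 - (1 - prob) / 2) * 100)
  out$Mean <- means; out$SD <- sds
  out[[paste0("HDI_", tails[1], "%")]] <- lo
  out[[paste0("HDI_", tails[2], "%")]] <- hi
  out$Rhat <- rh
  attr(out, "family") <- family
  out
}

#' Export a contrast as JSON
#'
#' @param contrast an [compare_abilities()] result.
#' @param path output JSON path.
#' @return invisible `NULL`.
#' @export
write_contrast <- function(contrast, path) {
  stopifnot(inherits(contrast, "mdnrm_contrast"))
  jsonlite::write_json(
    list(a = contrast$a, b = contrast$b, pd = contrast$pd,
         hdi = as.list(contrast$hdi), prob = contrast$prob,
         mean_diff = mean(contrast$diff_draws),
         significant = contrast$significant, variant = contrast$variant),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(NULL)
}

#' Plot a posterior ability contrast
#'
#' Two-panel base-graphics display: posterior histograms of the two
#' ability parameters, and the histogram of their difference with the
#' sign split shaded and the PD value annotated.
#'
#' @param x an [compare_abilities()] result.
#' @param ... ignored.
#' @return invisible `NULL`.
#' @export
plot.mdnrm_contrast <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(graphics::par(op))
  fmt_idx <- function(i) paste0("theta[", paste(i, collapse = ","), "]")
  rng <- range(c(x$draws_a, x$draws_b))
  ha <- graphics::hist(x$draws_a, breaks = 50, plot = FALSE)
  hb <- graphics::hist(x$draws_b, breaks = 50, plot = FALSE)
  graphics::plot(ha, col = grDevices::adjustcolor("steelblue", 0.6),
                 border = NA, xlim = rng, main = "posteriors",
                 xlab = "ability", freq = FALSE)
  graphics::plot(hb, col = grDevices::adjustcolor("firebrick", 0.6),
                 border = NA, freq = FALSE, add = TRUE)
  graphics::legend("topright", legend = c(fmt_idx(x$a), fmt_idx(x$b)),
                   fill = c("steelblue", "firebrick"), bty = "n")
  hd <- graphics::hist(x$diff_draws, breaks = 60, plot = FALSE)
  cols <- ifelse(hd$mids > 0, grDevices::adjustcolor("steelblue", 0.7),
                 grDevices::adjustcolor("grey60", 0.7))
  graphics::plot(hd, col = cols, border = NA,
                 main = sprintf("difference (PD = %.3f)", x$pd),
                 xlab = "difference", freq = FALSE)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(v = x$hdi, col = "firebrick")
  invisible(NULL)
}
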