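# Pareto-smoothed importance sampling (PSIS) leave-one-out cross-validation.
#
# Generalised Pareto tail fit via the Zhang & Stephens (2009) profile
# posterior-mean estimator with the usual weakly-informative shape
# regularisation; tail order statistics of the importance ratios are replaced
# by the fitted quantiles and truncated at the raw maximum.

# fit GPD(shape k, scale sigma) to positive exceedances; returns loo-style
# shape (k > 0 = heavy tail)
gpd_fit <- function(z) {
  z <- sort(z)
  n <- length(z)
  if (n < 5L || z[n] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- z[max(1L, floor(n / 4 + 0.5))]
  b <- 1 / z[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  profl <- vapply(b, function(bj) {
    kj <- -mean(log1p(-bj * z))
    n * (log(bj / kj) + kj - 1)
  }, numeric(1))
  w <- exp(profl - max(profl))
  w <- w / sum(w)
  bhat <- sum(b * w)
  k_zs <- -mean(log1p(-bhat * z))    # Zhang-Stephens shape = -xi
  sigma <- k_zs / bhat
  k <- -k_zs                         # loo-style shape (k > 0 = heavy tail)
  k <- (n * k + 5) / (n + 10)        # regularise towards 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma / k * ((1 - p)^(-k) - 1)
}

# smooth one vector of log importance ratios; returns normalised log weights
# and the Pareto-k diagnostic
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  if (M >= 5 && S - M >= 1) {
    ord <- order(lr)
    tail_idx <- ord[(S - M + 1):S]
    cutoff <- exp(lr[ord[S - M]])
    z <- exp(lr[tail_idx]) - cutoff
    if (any(z > 0)) {
      fit <- gpd_fit(z[z >= 0])
      khat <- fit$k
      if (is.finite(khat) && khat < 1) {
        q <- vapply((seq_len(M) - 0.5) / M, qgpd, numeric(1),
                    k = fit$k, sigma = fit$sigma)
        # assign fitted quantiles in ascending order of the raw tail
        sm <- log(cutoff + q)
        sm <- pmin(sm, 0)                       # truncate at raw maximum
        lr[tail_idx[order(lr[tail_idx])]] <- sm
      }
    }
  }
  list(log_weights = lr - logsumexp(lr), khat = khat)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' PSIS-LOO expected log predictive density
#'
#' Computes the leave-one-out expected log pointwise predictive density
#' (elpd) from a fitted model's pointwise log-likelihood matrix by
#' Pareto-smoothed importance sampling, with per-observation Pareto-k
#' diagnostics.
#'
#' @param fit an [allometry_fit] object (or a draws x observations
#'   log-likelihood matrix).
#' @return list of class `loo_elpd`: `elpd` (sum), `se`, `pointwise`,
#'   `pareto_k`, `n`.
#' @export
loo_elpd <- function(fit) {
  ll <- if (inherits(fit, "allometry_fit")) fit$log_lik else as.matrix(fit)
  n <- ncol(ll)
  pointwise <- numeric(n)
  pareto_k <- numeric(n)
  for (i in seq_len(n)) {
    sm <- psis_smooth(-ll[, i])
    pointwise[i] <- logsumexp(sm$log_weights + ll[, i])
    pareto_k[i] <- sm$khat
  }
  structure(list(elpd = sum(pointwise),
                 se = sqrt(n * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k, n = n),
            class = "loo_elpd")
}

#' @export
print.loo_elpd <- function(x, ...) {
  cat(sprintf("PSIS-LOO: elpd %.2f (se %.2f), n = %d, max Pareto k %.2f\n",
              x$elpd, x$se, x$n, suppressWarnings(max(x$pareto_k,
                                                      na.rm = TRUE))))
  invisible(x)
}

#' Compare two models by PSIS-LOO
#'
#' Both fits must be to the same observations in the same order. The
#' difference is `elpd_full - elpd_reduced` with its standard error from the
#' pointwise differences.
#'
#' @param fit_full the full-model [allometry_fit].
#' @param fit_reduced the reduced-model fit on the same data.
#' @return list of class `allometry_loo_compare`: `elpd_full`,
#'   `elpd_reduced`, `elpd_diff`, `se_diff`, `pareto_k_full`,
#'   `pareto_k_reduced`.
#' @export
loo_compare_fits <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "allometry_fit"),
            inherits(fit_reduced, "allometry_fit"))
  d1 <- fit_full$data
  d2 <- fit_reduced$data
  if (nrow(d1) != nrow(d2) || max(abs(d1$x - d2$x)) > 0 ||
      max(abs(d1$y - d2$y)) > 0 || !identical(d1$group, d2$group))
    stop("consistency error: fits use different observation sets")
  l1 <- loo_elpd(fit_full)
  l2 <- loo_elpd(fit_reduced)
  diff_pw <- l1$pointwise - l2$pointwise
  structure(list(elpd_full = l1$elpd, elpd_reduced = l2$elpd,
                 elpd_diff = l1$elpd - l2$elpd,
                 se_diff = sqrt(l1$n * stats::var(diff_pw)),
                 pareto_k_full = l1$pareto_k,
                 pareto_k_reduced = l2$pareto_k),
            class = "allometry_loo_compare")
}

#' @export
print.allometry_loo_compare <- function(x, ...) {
  cat(sprintf(paste0("elpd (full) %.2f | elpd (reduced) %.2f | ",
                     "diff %.2f (se %.2f)\n"),
              x$elpd_full, x$elpd_reduced, x$elpd_diff, x$se_diff))
  invisible(x)
}
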