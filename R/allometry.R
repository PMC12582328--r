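#' Prior specification for the allometric regression
#'
#' Weakly informative defaults: the overall slope prior is centred at 3/2
#' (volume scales with the cube of linear size, surface area with the
#' square); scale parameters get half-Cauchy priors. All `sd`/`scale` values
#' are standard deviations or Cauchy scales.
#'
#' @param alpha_mean,alpha_sd normal prior on the overall intercept.
#' @param sigma_intercept_scale half-Cauchy scale of the group-intercept sd.
#' @param beta_mean,beta_sd normal prior on the overall slope.
#' @param sigma_delta_scale half-Cauchy scale of the species slope-deviation
#'   sd (full model only).
#' @param sigma_gamma_scale half-Cauchy scale of the group slope-deviation
#'   sd.
#' @param sigma_obs_scale half-Cauchy scale of the observation noise sd.
#' @return named list of prior hyperparameters.
#' @export
allometry_prior <- function(alpha_mean = 0, alpha_sd = 20,
                            sigma_intercept_scale = 10,
                            beta_mean = 1.5, beta_sd = 10,
                            sigma_delta_scale = 50,
                            sigma_gamma_scale = 10,
                            sigma_obs_scale = 15) {
  list(alpha_mean = alpha_mean, alpha_sd = alpha_sd,
       sigma_intercept_scale = sigma_intercept_scale,
       beta_mean = beta_mean, beta_sd = beta_sd,
       sigma_delta_scale = sigma_delta_scale,
       sigma_gamma_scale = sigma_gamma_scale,
       sigma_obs_scale = sigma_obs_scale)
}

#' Hierarchical Bayesian allometric regression
#'
#' Fits the hierarchical regression of log10 inner-dendritic volume (`y`) on
#' log10 outer-dendritic surface area (`x`) across the four species x
#' neuron-type groups:
#' \deqn{y_i ~ N(\alpha_{g(i)} + \beta_{g(i)} x_i, \sigma_{obs})}
#' with noncentered group intercepts
#' \eqn{\alpha_g = \alpha_{overall} + \sigma_{intercept} z_g},
#' and group slopes
#' \eqn{\beta_g = \beta_{overall} + \delta_{s(g)} + \gamma_g}
#' (species deviation \eqn{\delta_s} plus within-species group deviation
#' \eqn{\gamma_g}). The reduced model omits \eqn{\delta_s}. Group slopes are
#' constrained nonnegative by rejection. Sampling is componentwise adaptive
#' random-walk Metropolis (scales on the log scale), run over independent
#' chains whose seeds derive deterministically from `seed`.
#'
#' @param data data frame with columns `x`, `y`, `species`, `neuron_type`
#'   (or a custom formula mapping via `formula`).
#' @param formula optional formula `response ~ predictor` naming the columns
#'   to use (default `y ~ x`).
#' @param model `"full"` (species slope deviation) or `"reduced"`.
#' @param chains number of MCMC chains (default 4).
#' @param warmup warm-up (adaptation) draws per chain, discarded (default
#'   1000).
#' @param samples retained post-warmup draws per chain (default 2000).
#' @param thin raw iterations per draw (default 5): each chain runs
#'   `(warmup + samples) * thin` iterations, adapts during the first
#'   `warmup * thin`, and keeps every `thin`-th of the rest — compensating
#'   for the shorter autocorrelation time a gradient-based sampler would
#'   achieve per iteration.
#' @param seed integer seed; per-chain seeds derive from it.
#' @param prior an [allometry_prior()] list.
#' @param constraint nonnegativity constraint: `"group"` (each
#'   \eqn{\beta_g \ge 0}, default), `"overall"` (\eqn{\beta_{overall} \ge 0}
#'   only), or `"none"`.
#' @param centered use the centered intercept parameterisation (sampling
#'   \eqn{\alpha_g} directly) instead of the noncentered default?
#' @param prior_only sample from the prior (likelihood off)?
#' @param sigma_obs_fixed optionally fix the observation sd at this value
#'   (useful for least-squares-limit checks); `NULL` estimates it.
#' @param init_step initial random-walk step size.
#' @return object of class `allometry_fit`; see Details. Methods:
#'   `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`.
#' @details The returned object contains `draws` (all raw parameters,
#'   post-warmup, all chains), derived per-draw `alpha_g`/`beta_g`/
#'   `sigma_obs`, the pointwise log-likelihood matrix for LOO, split-Rhat
#'   per raw parameter and per-parameter acceptance rates. A warning (never
#'   silence) is raised if any split-Rhat exceeds 1.01.
#' @export
allometry_fit <- function(data, formula = y ~ x,
                          model = c("full", "reduced"), chains = 4,
                          warmup = 1000, samples = 2000, thin = 5,
                          seed = 1L, prior = allometry_prior(),
                          constraint = c("group", "overall", "none"),
                          centered = FALSE, prior_only = FALSE,
                          sigma_obs_fixed = NULL, init_step = 0.1) {
  model <- match.arg(model)
  constraint <- match.arg(constraint)
  vars <- all.vars(formula)
  stopifnot(length(vars) == 2)
  df <- data.frame(y = as.numeric(data[[vars[1]]]),
                   x = as.numeric(data[[vars[2]]]),
                   species = as.character(data$species),
                   neuron_type = as.character(data$neuron_type))
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("data error: x and y must be finite")
  species_lv <- sort(unique(df$species))
  type_lv <- sort(unique(df$neuron_type))
  grp <- factor(paste(df$species, df$neuron_type, sep = "."),
                levels = as.vector(outer(type_lv, species_lv,
                                         function(t, s)
                                           paste(s, t, sep = "."))))
  if (any(is.na(grp))) stop("data error: unmapped group")
  group_table <- do.call(rbind, lapply(levels(grp), function(lv) {
    parts <- strsplit(lv, ".", fixed = TRUE)[[1]]
    data.frame(group = lv, species = parts[1], neuron_type = parts[2])
  }))
  tab <- table(grp)
  if (any(tab == 0)) stop("data error: empty group")
  min_n <- if (prior_only) 1L else if (model == "full") 2L else 1L
  if (any(tab < min_n))
    stop(sprintf("data error: every group needs at least %d observations",
                 min_n))
  g <- as.integer(grp)
  G <- nlevels(grp)
  sp_of_g <- match(group_table$species, species_lv)
  has_species <- model == "full"
  S <- length(species_lv)

  pr <- prior
  if (!is.null(sigma_obs_fixed)) {
    stopifnot(sigma_obs_fixed > 0)
  }

  # initial state: pooled least squares, scales at moderate values
  b_init <- stats::cov(df$x, df$y) / max(stats::var(df$x), 1e-12)
  if (constraint != "none") b_init <- max(b_init, 0.1)
  resid_sd <- max(stats::sd(df$y - b_init * df$x), 0.05)
  npar <- 2 + G + 1 + (if (has_species) 1 + S else 0) + 1 + G + 1
  init <- numeric(npar)
  init[1] <- mean(df$y - b_init * df$x)
  init[2] <- log(0.3)
  init[2 + G + 1] <- b_init
  if (has_species) init[2 + G + 2] <- log(0.3)
  init[npar - G - 1] <- log(0.3)
  init[npar] <- log(if (is.null(sigma_obs_fixed)) resid_sd else
    sigma_obs_fixed)
  if (centered) init[3:(2 + G)] <- init[1]

  p_names <- c("alpha_overall", "log_sigma_intercept",
               paste0(if (centered) "alpha[" else "z[", levels(grp), "]"),
               "beta_overall",
               if (has_species) c("log_sigma_delta",
                                  paste0("delta[", species_lv, "]")),
               "log_sigma_gamma", paste0("gamma[", levels(grp), "]"),
               "log_sigma_obs")

  keep <- samples
  chain_draws <- vector("list", chains)
  accepts <- matrix(NA_real_, chains, npar)
  for (ch in seq_len(chains)) {
    chain_seed <- as.integer((as.numeric(seed) * 1000 + 104729 * ch) %%
                               2147483647)
    init_ch <- with_seed(chain_seed, function() {
      out <- init + stats::rnorm(npar, 0, 0.02)
      if (constraint != "none") out[2 + G + 1] <- abs(out[2 + G + 1])
      out
    })
    res <- with_seed(chain_seed + 1L, function()
      .allometry_chain(df$x, df$y, g, sp_of_g, has_species, centered,
                       prior_only, match(constraint,
                                         c("group", "overall", "none")) - 1L,
                       pr, as.integer((warmup + samples) * thin),
                       as.integer(warmup * thin), as.integer(thin), init_ch,
                       init_step,
                       if (is.null(sigma_obs_fixed)) -1 else
                         sigma_obs_fixed))
    colnames(res$draws) <- p_names
    chain_draws[[ch]] <- res$draws
    accepts[ch, ] <- res$accept
  }

  rhat <- split_rhat(chain_draws)
  draws <- do.call(rbind, chain_draws)
  chain_id <- rep(seq_len(chains), each = keep)

  # derived quantities per draw
  a0 <- draws[, "alpha_overall"]
  sint <- exp(draws[, "log_sigma_intercept"])
  zcols <- 3:(2 + G)
  alpha_g <- if (centered) draws[, zcols, drop = FALSE] else
    a0 + sint * draws[, zcols, drop = FALSE]
  colnames(alpha_g) <- paste0("alpha[", levels(grp), "]")
  b0 <- draws[, "beta_overall"]
  delta <- if (has_species)
    draws[, paste0("delta[", species_lv, "]"), drop = FALSE] else
      matrix(0, nrow(draws), S)
  gam <- draws[, paste0("gamma[", levels(grp), "]"), drop = FALSE]
  beta_g <- b0 + delta[, sp_of_g, drop = FALSE] + gam
  colnames(beta_g) <- paste0("beta[", levels(grp), "]")
  sigma_obs <- if (is.null(sigma_obs_fixed)) exp(draws[, "log_sigma_obs"])
  else rep(sigma_obs_fixed, nrow(draws))

  # pointwise log-likelihood (draws x observations)
  n <- nrow(df)
  log_lik <- matrix(NA_real_, nrow(draws), n)
  for (i in seq_len(n)) {
    mu <- alpha_g[, g[i]] + beta_g[, g[i]] * df$x[i]
    log_lik[, i] <- stats::dnorm(df$y[i], mu, sigma_obs, log = TRUE)
  }

  fit <- structure(
    list(model = model, draws = draws, chain_id = chain_id,
         chains = chains, warmup = warmup, samples = samples, thin = thin,
         seed = seed, prior = pr, constraint = constraint,
         centered = centered, prior_only = prior_only,
         data = cbind(df, group = grp), group_table = group_table,
         species_levels = species_lv, g = g, sp_of_g = sp_of_g,
         alpha_g = alpha_g, beta_g = beta_g, sigma_obs = sigma_obs,
         log_lik = log_lik, rhat = rhat,
         accept = colMeans(accepts)),
    class = "allometry_fit")
  bad <- rhat > 1.01
  if (!prior_only && any(bad, na.rm = TRUE))
    warning(sprintf(
      "possible non-convergence: split-Rhat > 1.01 for %s (max %.3f)",
      paste(p_names[which(bad)], collapse = ", "), max(rhat, na.rm = TRUE)))
  fit
}

# split-Rhat over a list of per-chain draw matrices
split_rhat <- function(chain_draws) {
  npar <- ncol(chain_draws[[1]])
  n <- nrow(chain_draws[[1]])
  half <- n %/% 2
  vapply(seq_len(npar), function(j) {
    halves <- unlist(lapply(chain_draws, function(m)
      list(m[seq_len(half), j], m[(half + 1):(2 * half), j])),
      recursive = FALSE)
    means <- vapply(halves, mean, numeric(1))
    vars <- vapply(halves, stats::var, numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W <= 0) return(NA_real_)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical allometric regression (%s model%s)\n", x$model,
    if (x$prior_only) ", prior only" else ""))
  cat(sprintf("  %d observations, %d groups; %d chains x %d draws\n",
              nrow(x$data), nrow(x$group_table), x$chains, x$samples))
  cat("  posterior mean group slopes:\n")
  b <- colMeans(x$beta_g)
  for (i in seq_along(b)) cat(sprintf("    %s = %.3f\n", names(b)[i], b[i]))
  cat(sprintf("  max split-Rhat %.3f; mean acceptance %.2f\n",
              max(x$rhat, na.rm = TRUE), mean(x$accept)))
  invisible(x)
}

#' @export
summary.allometry_fit <- function(object, probs = c(0.05, 0.5, 0.95), ...) {
  raw <- object$draws
  der <- cbind(object$alpha_g, object$beta_g,
               sigma_obs = object$sigma_obs)
  all <- cbind(raw, der)
  qs <- t(apply(all, 2, stats::quantile, probs = probs))
  out <- data.frame(mean = colMeans(all), sd = apply(all, 2, stats::sd), qs,
                    check.names = FALSE)
  out$rhat <- c(object$rhat, rep(NA_real_, ncol(der)))
  out
}

#' @export
coef.allometry_fit <- function(object, ...) {
  cbind(alpha = colMeans(object$alpha_g), beta = colMeans(object$beta_g))
}

#' @export
fitted.allometry_fit <- function(object, ...) {
  g <- object$g
  vapply(seq_along(g), function(i)
    mean(object$alpha_g[, g[i]] + object$beta_g[, g[i]] *
           object$data$x[i]), numeric(1))
}

#' @export
residuals.allometry_fit <- function(object, ...) {
  object$data$y - fitted(object)
}

#' @export
predict.allometry_fit <- function(object, newdata = NULL,
                                  interval = c("credible", "predictive",
                                               "none"),
                                  level = 0.90, ...) {
  interval <- match.arg(interval)
  if (is.null(newdata)) newdata <- object$data
  lv <- object$group_table$group
  gl <- paste(newdata$species, newdata$neuron_type, sep = ".")
  gi <- match(gl, lv)
  if (any(is.na(gi))) stop("data error: newdata contains unknown groups")
  a <- (1 - level) / 2
  out <- data.frame(fit = numeric(nrow(newdata)))
  if (interval != "none") out$lwr <- out$upr <- NA_real_
  for (i in seq_len(nrow(newdata))) {
    mu <- object$alpha_g[, gi[i]] + object$beta_g[, gi[i]] * newdata$x[i]
    if (interval == "predictive")
      mu <- mu + stats::rnorm(length(mu), 0, object$sigma_obs)
    out$fit[i] <- mean(mu)
    if (interval != "none") {
      q <- stats::quantile(mu, c(a, 1 - a), names = FALSE)
      out$lwr[i] <- q[1]
      out$upr[i] <- q[2]
    }
  }
  out
}

#' @export
simulate.allometry_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  S <- nrow(object$beta_g)
  g <- object$g
  x <- object$data$x
  out <- replicate(nsim, {
    s <- sample.int(S, 1)
    stats::rnorm(length(x),
                 object$alpha_g[s, g] + object$beta_g[s, g] * x,
                 object$sigma_obs[s])
  })
  as.data.frame(out)
}

#' @export
plot.allometry_fit <- function(x, ...) {
  df <- x$data
  cols <- c("#1f6fb4", "#7fb2d9", "#c23b22", "#e69d8f")
  gi <- as.integer(df$group)
  graphics::plot(df$x, df$y, col = cols[gi], pch = 16,
                 xlab = expression(log[10] ~ "outer-dendritic surface area"),
                 ylab = expression(log[10] ~ "inner-dendritic volume"), ...)
  cf <- coef(x)
  for (k in seq_len(nrow(cf))) {
    rng <- range(df$x[gi == k])
    graphics::lines(rng, cf[k, "alpha"] + cf[k, "beta"] * rng,
                    col = cols[k], lwd = 2)
  }
  graphics::legend("topleft", legend = x$group_table$group, col = cols,
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Posterior species slope difference
#'
#' Per-draw difference between the species' mean group slopes
#' (Drosophila minus Aedes, i.e. second species level minus first), with the
#' posterior mean, a 5-95% credible interval and the posterior probability
#' that the difference is positive. Only meaningful for the full model.
#'
#' @param fit a full-model [allometry_fit].
#' @param probs credible-interval probabilities (default `c(0.05, 0.95)`).
#' @return list with `mean`, `interval`, `prob_positive`, `draws`.
#' @export
species_slope_difference <- function(fit, probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "allometry_fit"))
  if (fit$model != "full")
    stop("unsupported operation: species slope difference requires the ",
         "full model")
  sp <- fit$sp_of_g
  m1 <- rowMeans(fit$beta_g[, sp == 1, drop = FALSE])
  m2 <- rowMeans(fit$beta_g[, sp == 2, drop = FALSE])
  d <- m2 - m1
  list(mean = mean(d),
       interval = stats::quantile(d, probs, names = FALSE),
       prob_positive = mean(d > 0), draws = d,
       species = fit$species_levels)
}
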