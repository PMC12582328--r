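test_that("with tiny fixed noise the posterior collapses to least squares", {
  set.seed(42)
  x <- runif(50, 0, 3)
  df <- data.frame(x = x, y = 1 + 2 * x, species = "Aedes",
                   neuron_type = "CO2")
  fit <- suppressWarnings(allometry_fit(df, sigma_obs_fixed = 0.01,
                                        seed = 7))
  cf <- coef(fit)
  expect_lt(abs(cf[1, "beta"] - 2), 0.05)
  expect_lt(abs(cf[1, "alpha"] - 1), 0.05)
})

test_that("group structure and data validation are enforced", {
  df <- simulate_allometry(n_per_group = 5, seed = 1)
  expect_error(allometry_fit(df[df$species == "Aedes" |
                                  df$neuron_type == "CO2", ]),
               "data error")
  df_bad <- df
  df_bad$y[1] <- NA
  expect_error(allometry_fit(df_bad), "finite")
})

test_that("group slopes are nonnegative in every draw", {
  # weak data pulls slopes toward the prior; the constraint still holds
  df <- simulate_allometry(n_per_group = 3, seed = 6, beta_overall = 0.1,
                           sigma_obs = 0.5)
  fit <- quick_fit(df, seed = 2)
  expect_true(all(fit$beta_g >= 0))
})

test_that("a simulated species slope gap is recovered", {
  df <- simulate_allometry(n_per_group = 20, seed = 3, delta = c(0, 0.6),
                           sigma_obs = 0.15)
  fit <- suppressWarnings(allometry_fit(df, seed = 11))
  d <- species_slope_difference(fit)
  expect_gt(d$prob_positive, 0.9)
  expect_lt(abs(d$mean - 0.6), 0.25)
  # reduced model refuses the species contrast
  fr <- quick_fit(df, model = "reduced", seed = 11)
  expect_error(species_slope_difference(fr), "unsupported")
})

test_that("equal species slopes give an undecided posterior difference", {
  # per-dataset Pr(delta > 0) follows the data's own slope fluctuation, so
  # the null check is on the average over replicate simulations
  pr <- vapply(1:16, function(s) {
    df <- simulate_allometry(n_per_group = 20, seed = 300 + s,
                             delta = c(0, 0), sigma_obs = 0.15)
    fit <- quick_fit(df, seed = 5)
    species_slope_difference(fit)$prob_positive
  }, numeric(1))
  expect_gt(mean(pr), 0.25)
  expect_lt(mean(pr), 0.75)
})

test_that("the species difference flips sign under relabelling", {
  df <- simulate_allometry(n_per_group = 15, seed = 13, delta = c(0, 0.5))
  fit <- quick_fit(df, seed = 3)
  df_sw <- df
  df_sw$species <- c(Aedes = "Drosophila", Drosophila = "Aedes")[df$species]
  fit_sw <- quick_fit(df_sw, seed = 3)
  d <- species_slope_difference(fit)
  d_sw <- species_slope_difference(fit_sw)
  expect_lt(abs(d$mean + d_sw$mean), 0.1)
})

test_that("fitting the reduced model to shared-slope data centres contrasts at zero", {
  df <- simulate_allometry(n_per_group = 20, seed = 17, delta = c(0, 0),
                           gamma = c(0, 0, 0, 0), sigma_obs = 0.15)
  fit <- quick_fit(df, model = "reduced", seed = 9)
  for (a in 1:3) for (b in (a + 1):4) {
    dd <- fit$beta_g[, a] - fit$beta_g[, b]
    expect_lt(abs(mean(dd)), 2 * sd(dd))
  }
})

test_that("prior-only sampling reproduces the stated prior families", {
  df <- simulate_allometry(n_per_group = 2, seed = 1)
  fit <- suppressWarnings(
    allometry_fit(df, prior_only = TRUE, constraint = "none", chains = 4,
                  warmup = 500, samples = 1000, thin = 25, seed = 123))
  draws <- fit$draws
  sub <- seq(1, nrow(draws), length.out = 4000)
  phalf <- function(scale) function(q) 2 * (pcauchy(q, 0, scale) - 0.5)
  expect_gt(ks.test(exp(draws[sub, "log_sigma_obs"]), phalf(15))$p.value,
            0.01)
  expect_gt(ks.test(exp(draws[sub, "log_sigma_intercept"]),
                    phalf(10))$p.value, 0.01)
  expect_gt(ks.test(exp(draws[sub, "log_sigma_delta"]), phalf(50))$p.value,
            0.01)
  expect_gt(ks.test(draws[sub, "alpha_overall"], "pnorm", 0, 20)$p.value,
            0.01)
  expect_gt(ks.test(draws[sub, "beta_overall"], "pnorm", 1.5, 10)$p.value,
            0.01)
})

test_that("centered and noncentered parameterisations agree", {
  df <- simulate_allometry(n_per_group = 50, seed = 19, sigma_obs = 0.1)
  f_nc <- suppressWarnings(allometry_fit(df, seed = 21))
  f_c <- suppressWarnings(allometry_fit(df, seed = 22, centered = TRUE))
  expect_lt(max(abs(colMeans(f_nc$alpha_g) - colMeans(f_c$alpha_g))), 0.05)
  expect_lt(max(abs(colMeans(f_nc$beta_g) - colMeans(f_c$beta_g))), 0.05)
})

test_that("the posterior is invariant to permuting data rows", {
  df <- simulate_allometry(n_per_group = 15, seed = 23)
  set.seed(1)
  perm <- sample(nrow(df))
  f1 <- quick_fit(df, seed = 31)
  f2 <- quick_fit(df[perm, ], seed = 31)
  expect_lt(max(abs(colMeans(f1$beta_g) - colMeans(f2$beta_g))), 0.05)
  expect_lt(max(abs(colMeans(f1$alpha_g) - colMeans(f2$alpha_g))), 0.08)
})

test_that("an independent Gibbs-sampler implementation agrees on the posterior", {
  # rjags fits the same hierarchy (no slope constraint; the data keep all
  # slopes far from zero, so the constraint never binds)
  df <- simulate_allometry(n_per_group = 25, seed = 29, delta = c(0, 0.5),
                           sigma_obs = 0.12)
  fit <- suppressWarnings(allometry_fit(df, seed = 33))

  model_txt <- "
  model {
    for (i in 1:n) { y[i] ~ dnorm(alpha[g[i]] + beta[g[i]] * x[i], tau) }
    for (k in 1:G) {
      z[k] ~ dnorm(0, 1)
      alpha[k] <- a0 + sint * z[k]
      gam[k] ~ dnorm(0, pow(sgamma, -2))
      beta[k] <- b0 + delta[sp[k]] + gam[k]
    }
    for (s in 1:S) { delta[s] ~ dnorm(0, pow(sdelta, -2)) }
    a0 ~ dnorm(0, pow(20, -2))
    b0 ~ dnorm(1.5, pow(10, -2))
    sint ~ dt(0, pow(10, -2), 1) T(0,)
    sdelta ~ dt(0, pow(50, -2), 1) T(0,)
    sgamma ~ dt(0, pow(10, -2), 1) T(0,)
    sobs ~ dt(0, pow(15, -2), 1) T(0,)
    tau <- pow(sobs, -2)
  }"
  g <- as.integer(factor(paste(df$species, df$neuron_type, sep = "."),
                         levels = fit$group_table$group))
  jm <- rjags::jags.model(textConnection(model_txt),
                          data = list(x = df$x, y = df$y, g = g, n = nrow(df),
                                      G = 4, S = 2, sp = fit$sp_of_g),
                          n.chains = 2, quiet = TRUE,
                          inits = list(.RNG.name = "base::Mersenne-Twister",
                                       .RNG.seed = 99))
  update(jm, 2000, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("alpha", "beta", "sobs"), 10000,
                            progress.bar = "none")
  jag <- colMeans(do.call(rbind, lapply(sm, as.matrix)))
  expect_lt(max(abs(colMeans(fit$beta_g) -
                      jag[paste0("beta[", 1:4, "]")])), 0.06)
  expect_lt(max(abs(colMeans(fit$alpha_g) -
                      jag[paste0("alpha[", 1:4, "]")])), 0.09)
  expect_lt(abs(mean(fit$sigma_obs) - jag["sobs"]), 0.03)
})

test_that("PSIS-LOO matches brute-force leave-one-out on a small dataset", {
  set.seed(2)
  x <- seq(0.5, 2.5, length.out = 8)
  df <- data.frame(x = x, y = 0.5 + 1.5 * x + rnorm(8, 0, 0.15),
                   species = "Aedes", neuron_type = "CO2")
  fit <- suppressWarnings(allometry_fit(df, model = "reduced", seed = 4))
  l <- loo_elpd(fit)
  bf <- sum(brute_force_loo(df, "reduced", seed = 4))
  expect_lt(abs(l$elpd - bf), 2 * l$se)
})

test_that("LOO self-comparison is exactly zero", {
  df <- simulate_allometry(n_per_group = 5, seed = 8)
  fit <- quick_fit(df, seed = 12)
  cmp <- loo_compare_fits(fit, fit)
  expect_identical(cmp$elpd_diff, 0)
  expect_identical(cmp$se_diff, 0)
})

test_that("LOO prefers the full model when a species slope gap exists", {
  wins <- vapply(1:20, function(s) {
    df <- simulate_allometry(n_per_group = 25, seed = 700 + s,
                             delta = c(0, 0.8), sigma_obs = 0.1)
    # elpd differences are subtle; use enough draws to resolve them
    ff <- suppressWarnings(allometry_fit(df, seed = 41, chains = 2,
                                         warmup = 500, samples = 1000,
                                         thin = 4))
    fr <- suppressWarnings(allometry_fit(df, model = "reduced", seed = 41,
                                         chains = 2, warmup = 500,
                                         samples = 1000, thin = 4))
    loo_compare_fits(ff, fr)$elpd_diff > 0
  }, logical(1))
  expect_gte(mean(wins), 0.8)
})

test_that("mismatched observation sets cannot be compared", {
  d1 <- simulate_allometry(n_per_group = 5, seed = 2)
  d2 <- simulate_allometry(n_per_group = 5, seed = 3)
  f1 <- quick_fit(d1, seed = 1)
  f2 <- quick_fit(d2, seed = 1)
  expect_error(loo_compare_fits(f1, f2), "consistency error")
})

test_that("fit methods expose the usual modelling interface", {
  df <- simulate_allometry(n_per_group = 10, seed = 44)
  fit <- quick_fit(df, seed = 2)
  expect_output(print(fit), "group slopes")
  sm <- summary(fit)
  expect_true(all(c("mean", "sd", "rhat") %in% names(sm)))
  expect_equal(dim(coef(fit)), c(4L, 2L))
  expect_length(fitted(fit), nrow(df))
  expect_equal(residuals(fit), df$y - fitted(fit), ignore_attr = TRUE)
  pr <- predict(fit, data.frame(x = c(1, 2), species = "Aedes",
                                neuron_type = "CO2"))
  expect_true(all(pr$lwr < pr$fit & pr$fit < pr$upr))
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(nrow(df), 3L))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(fit))
  grDevices::dev.off()
})
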