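#' Prior specification for fixed effects
#'
#' Weakly-informative student-t priors: mean 0, 3 degrees of freedom, scale 10
#' in standardized units (the scale is multiplied by `sd(y)/sd(x)` per
#' coefficient when the model is built, so 10 is on the standardized scale).
#'
#' @param df degrees of freedom.
#' @param location prior mean.
#' @param scale prior scale in standardized units.
#' @export
prior_spec <- function(df = 3, location = 0, scale = 10) {
  structure(list(family = "student_t", df = df, location = location,
                 scale = scale), class = "prior_spec")
}

# Generic Bayesian linear mixed model via JAGS: y = X b + u[group1]
# (+ v[group2]) (+ s[group1] * slope_var), gaussian or student-t likelihood.
# 4 chains, 1000 warmup + 1000 sampling draws per chain (sampler settings per
# the study's MCMC configuration). Returns draws for the fixed effects and a
# convergence flag from split-Rhat (< 1.01).
jags_lmm <- function(y, X, group1, group2 = NULL, slope_x = NULL,
                     robust = FALSE, priors = prior_spec(), seed = 1,
                     n_chains = 4, n_warmup = 1000, n_iter = 1000,
                     monitor_extra = character()) {
  sd_y <- sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  # center non-constant columns for sampler mixing; coefficients other than
  # the intercept are unchanged by this reparametrization, and the intercept
  # is mapped back after sampling
  x_mean <- colMeans(X)
  is_const <- apply(X, 2, function(v) sd(v) == 0)
  x_mean[is_const] <- 0
  Xc <- sweep(X, 2, x_mean)
  sd_x <- apply(X, 2, sd)
  prior_scale <- ifelse(sd_x > 0, priors$scale * sd_y / sd_x,
                        priors$scale * sd_y)

  has_g2 <- !is.null(group2)
  has_slope <- !is.null(slope_x)
  lik <- if (robust) {
    "y[i] ~ dt(mu[i], tau, nu)"
  } else {
    "y[i] ~ dnorm(mu[i], tau)"
  }
  mu <- paste0("mu[i] <- inprod(X[i,], b) + u[g1[i]]",
               if (has_g2) " + v[g2[i]]" else "",
               if (has_slope) " + s[g1[i]] * sx[i]" else "")
  model_str <- paste0("model {\n",
    "  for (i in 1:N) {\n    ", mu, "\n    ", lik, "\n  }\n",
    "  for (j in 1:P) { b[j] ~ dt(prior_loc, pow(prior_sc[j], -2), prior_df) }\n",
    "  for (k in 1:J1) { u[k] ~ dnorm(0, tau_u) }\n",
    if (has_g2) "  for (k in 1:J2) { v[k] ~ dnorm(0, tau_v) }\n" else "",
    if (has_slope) "  for (k in 1:J1) { s[k] ~ dnorm(0, tau_s) }\n" else "",
    "  sigma ~ dt(0, pow(sd_y * 2.5, -2), 3) T(0,)\n",
    "  tau <- pow(sigma, -2)\n",
    "  sigma_u ~ dt(0, pow(sd_y * 2.5, -2), 3) T(0,)\n",
    "  tau_u <- pow(sigma_u, -2)\n",
    if (has_g2) "  sigma_v ~ dt(0, pow(sd_y * 2.5, -2), 3) T(0,)\n  tau_v <- pow(sigma_v, -2)\n" else "",
    if (has_slope) "  sigma_s ~ dt(0, pow(sd_y, -2), 3) T(0,)\n  tau_s <- pow(sigma_s, -2)\n" else "",
    if (robust) "  nu ~ dgamma(2, 0.1) T(2,)\n" else "",
    "}\n")

  dat <- list(y = y, X = Xc, N = length(y), P = ncol(X),
              g1 = as.integer(factor(group1)),
              J1 = length(unique(group1)),
              prior_loc = priors$location, prior_sc = prior_scale,
              prior_df = priors$df, sd_y = sd_y)
  if (has_g2) {
    dat$g2 <- as.integer(factor(group2))
    dat$J2 <- length(unique(group2))
  }
  if (has_slope) dat$sx <- slope_x

  inits <- lapply(seq_len(n_chains), function(k)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = child_seed(seed, k)))
  jm <- rjags::jags.model(textConnection(model_str), data = dat,
                          inits = inits, n.chains = n_chains,
                          n.adapt = 500, quiet = TRUE)
  update(jm, n_warmup, progress.bar = "none")
  monitors <- unique(c("b", "sigma", "sigma_u", monitor_extra))
  samp <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                              progress.bar = "none")

  rhat_ok <- TRUE
  gd <- try(coda::gelman.diag(samp[, grep("^b($|\\[)", coda::varnames(samp)),
                                   drop = FALSE],
                              autoburnin = FALSE, multivariate = FALSE),
            silent = TRUE)
  if (!inherits(gd, "try-error")) {
    rhat_ok <- all(gd$psrf[, 1] < 1.01, na.rm = TRUE)
  }
  draws <- as.matrix(samp)
  b_idx <- grep("^b($|\\[)", colnames(draws))
  b_draws <- draws[, b_idx, drop = FALSE]
  colnames(b_draws) <- colnames(X)
  # map the intercept back to the uncentered parametrization
  if (any(is_const)) {
    ic <- which(is_const)[1]
    shift <- b_draws[, !is_const, drop = FALSE] %*% x_mean[!is_const]
    b_draws[, ic] <- b_draws[, ic] - drop(shift) / X[1, ic]
    draws[, b_idx[ic]] <- b_draws[, ic]
  }
  list(b_draws = b_draws, draws = draws, converged = rhat_ok,
       model_string = model_str)
}

# posterior median + equal-tailed 95% interval per column of a draws matrix
summarize_draws <- function(draws) {
  tibble::tibble(term = colnames(draws),
                 estimate = unname(apply(draws, 2, median)),
                 lower = unname(apply(draws, 2, quantile, 0.025)),
                 upper = unname(apply(draws, 2, quantile, 0.975)))
}
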