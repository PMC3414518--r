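#' Prior specification for the rate-model parameters
#'
#' Proper, weakly informative defaults: half-normal priors for positive
#' parameters (baseline rates, transient strengths, decay rate, relative
#' influence of learning, random-effect SDs), uniform(0,1) for the
#' learning rates, and zero-centred normals for covariate effects.
#' Random-effect values are given hierarchical normal priors with the
#' current `sigma_ind` / `sigma_group` as SD.  Every scale is
#' overridable.
#'
#' @param r_scale,beta_sd,sigma_scale,gamma_scale,g_scale,rho_scale prior
#'   scales (half-normal SD, or normal SD for `beta`).
#' @return an object of class `smfm_priors`.
#' @export
prior_spec <- function(r_scale = 0.01, beta_sd = 2, sigma_scale = 1,
                       gamma_scale = 10, g_scale = 50, rho_scale = 1) {
  structure(list(r_scale = r_scale, beta_sd = beta_sd,
                 sigma_scale = sigma_scale, gamma_scale = gamma_scale,
                 g_scale = g_scale, rho_scale = rho_scale),
            class = "smfm_priors")
}

ld_halfnormal <- function(x, scale) {
  ifelse(x < 0, -Inf, log(2) + dnorm(x, 0, scale, log = TRUE))
}

# transform kind for a free-parameter name
param_transform <- function(name) {
  if (grepl("^(r_|gamma$|g_|rho$|sigma_)", name)) "log"
  else if (grepl("^(lambda_|s_)", name)) "logit"
  else "identity"
}

to_natural <- function(theta, transform) {
  switch(transform,
         log = exp(theta),
         logit = 1 / (1 + exp(-theta)),
         identity = theta)
}

from_natural <- function(x, transform) {
  switch(transform, log = log(x), logit = log(x / (1 - x)), identity = x)
}

# write one free parameter (natural scale) into an smfm_params
set_param <- function(params, name, value) {
  if (name %in% c("r_flap", "r_tube")) {
    params$r[[sub("r_", "", name)]] <- value
  } else if (grepl("^beta_", name)) {
    params$beta[[sub("beta_", "", name)]] <- value
  } else if (grepl("^lambda_", name)) {
    params$lambda[[sub("lambda_", "", name)]] <- value
  } else if (grepl("^s_", name)) {
    params$s[[sub("s_", "", name)]] <- value
  } else if (name == "gamma") {
    params$gamma <- value
  } else if (name == "rho") {
    params$rho <- value
  } else if (name %in% c("sigma_ind", "sigma_group")) {
    params[[name]] <- value
  } else if (grepl("^g_(general|box|sametype|specific)$", name)) {
    params[[name]][] <- value  # shared across age groups
  } else if (grepl("^g_(general|box|sametype|specific)_", name)) {
    kern <- sub("^(g_[a-z]+)_.*$", "\\1", name)
    age <- sub("^g_[a-z]+_", "", name)
    params[[kern]][[age]] <- value
  } else if (grepl("^u\\.", name)) {
    params$u[[sub("^u\\.", "", name)]] <- value
  } else if (grepl("^v\\.", name)) {
    params$v[[sub("^v\\.", "", name)]] <- value
  } else stop("unknown parameter name: ", name, call. = FALSE)
  params
}

# read one free parameter from an smfm_params (natural scale)
get_param <- function(params, name) {
  if (name %in% c("r_flap", "r_tube")) params$r[[sub("r_", "", name)]]
  else if (grepl("^beta_", name)) params$beta[[sub("beta_", "", name)]]
  else if (grepl("^lambda_", name)) params$lambda[[sub("lambda_", "", name)]]
  else if (grepl("^s_", name)) params$s[[sub("s_", "", name)]]
  else if (name == "gamma") params$gamma
  else if (name == "rho") params$rho
  else if (name %in% c("sigma_ind", "sigma_group")) params[[name]]
  else if (grepl("^g_(general|box|sametype|specific)$", name))
    unname(params[[name]][1])
  else if (grepl("^g_(general|box|sametype|specific)_", name)) {
    kern <- sub("^(g_[a-z]+)_.*$", "\\1", name)
    params[[kern]][[sub("^g_[a-z]+_", "", name)]]
  }
  else if (grepl("^u\\.", name)) {
    id <- sub("^u\\.", "", name)
    if (id %in% names(params$u)) params$u[[id]] else 0
  }
  else if (grepl("^v\\.", name)) {
    id <- sub("^v\\.", "", name)
    if (id %in% names(params$v)) params$v[[id]] else 0
  }
  else stop("unknown parameter name: ", name, call. = FALSE)
}

#' MCMC sampler configuration
#'
#' @param n_chains number of chains (`>= 2` for convergence diagnostics;
#'   1 is allowed for quick exploratory runs).
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in iterations discarded (adaptation happens here).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer random seed.
#' @return an object of class `smfm_mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, n_iter = 4000, n_burn = 1500,
                        thin = 1, seed = 1) {
  stopifnot(n_iter > n_burn, n_burn >= 0, n_chains >= 1, thin >= 1)
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burn = n_burn,
                 thin = thin, seed = as.integer(seed)),
            class = "smfm_mcmc_config")
}

#' Adaptive random-walk Metropolis sampler
#'
#' Block adaptive Metropolis on an unconstrained parameter vector: each
#' block proposes from a multivariate normal whose covariance tracks the
#' running sample covariance (scaled by `2.38^2 / d`) with a global scale
#' tuned towards the standard acceptance target (0.44 for scalar blocks,
#' 0.234 otherwise).  Adaptation happens during burn-in only, so the
#' retained chain is a valid Markov chain.
#'
#' This is the engine behind [run_mcmc()] and is exported so that any
#' log-density can be sampled (e.g. for sampler verification against
#' known distributions).
#'
#' @param log_target function of the parameter vector returning the
#'   (unnormalized) log density; `-Inf` allowed.
#' @param init numeric initial vector (must have finite log density).
#' @param config an [mcmc_config()] (single chain; `run_mcmc` handles
#'   multiple chains).
#' @param blocks list of integer index vectors partitioning the
#'   parameters; default one block with all of them.
#' @return list with `draws` (kept iterations x parameters), `lt` (log
#'   target per kept draw) and `acceptance` per block.
#' @export
adaptive_metropolis <- function(log_target, init, config = mcmc_config(),
                                blocks = NULL) {
  d <- length(init)
  if (is.null(blocks)) blocks <- list(seq_len(d))
  theta <- as.numeric(init)
  lt <- log_target(theta)
  if (!is.finite(lt))
    stop("initial parameter vector has non-finite log target ",
         "(initialization error)", call. = FALSE)
  nb <- length(blocks)
  mu <- lapply(blocks, function(b) theta[b])
  cv <- lapply(blocks, function(b) diag(length(b)) * 0.01)
  lsc <- vapply(blocks, function(b) log(2.38 / sqrt(length(b))), 0.0)
  targ <- vapply(blocks, function(b) if (length(b) == 1) 0.44 else 0.234, 0.0)
  acc_n <- acc_y <- numeric(nb)
  n_keep <- (config$n_iter - config$n_burn) %/% config$thin
  draws <- matrix(NA_real_, n_keep, d)
  lts <- numeric(n_keep)
  kept <- 0L
  chol_cache <- lapply(seq_len(nb), function(j)
    chol(cv[[j]] + diag(length(blocks[[j]])) * 1e-10))
  for (i in seq_len(config$n_iter)) {
    for (j in seq_len(nb)) {
      b <- blocks[[j]]
      prop <- theta
      z <- rnorm(length(b))
      prop[b] <- theta[b] + exp(lsc[j]) * drop(z %*% chol_cache[[j]])
      lt_p <- log_target(prop)
      a <- if (is.finite(lt_p)) min(1, exp(lt_p - lt)) else 0
      if (runif(1) < a) { theta <- prop; lt <- lt_p }
      if (i <= config$n_burn) {
        # Robbins-Monro scale tuning + running covariance
        lsc[j] <- lsc[j] + min(0.1, 1 / sqrt(i)) * (a - targ[j])
        del <- theta[b] - mu[[j]]
        mu[[j]] <- mu[[j]] + del / (i + 1)
        cv[[j]] <- cv[[j]] * (i / (i + 1)) +
          tcrossprod(del, theta[b] - mu[[j]]) / (i + 1)
        if (i %% 25 == 0 && i > 2 * length(b))
          chol_cache[[j]] <- chol(cv[[j]] + diag(length(b)) * 1e-10)
      } else {
        acc_n[j] <- acc_n[j] + 1; acc_y[j] <- acc_y[j] + a
      }
    }
    if (i > config$n_burn && (i - config$n_burn) %% config$thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- theta
      lts[kept] <- lt
    }
  }
  list(draws = draws[seq_len(kept), , drop = FALSE],
       lt = lts[seq_len(kept)],
       acceptance = ifelse(acc_n > 0, acc_y / acc_n, NA_real_))
}

#' Fit the rate model by MCMC
#'
#' Posterior sampling of a chosen set of free parameters by blocked
#' adaptive random-walk Metropolis on log/logit-transformed parameters,
#' targeting prior x likelihood.  Parameters not listed in `free` stay at
#' their values in `init_params`.  Random effects (`u.<id>` / `v.<group>`)
#' form their own proposal block.
#'
#' @param log a validated [event_log()] (or supply `data`).
#' @param variant an [smfm_variant()].
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param free character vector of free parameter names (e.g. `"r_flap"`,
#'   `"lambda_subordinate"`, `"s_entry"`, `"g_specific"`, `"rho"`,
#'   `"beta_sexM"`, `"u.IND3"`).
#' @param init_params an [smfm_params()] giving fixed values and starting
#'   points; defaults to [default_init()].
#' @param data optional precompiled [prepare_likelihood_data()].
#' @return an object of class `smfm_chains`.
#' @export
run_mcmc <- function(log = NULL, variant = smfm_variant(),
                     priors = prior_spec(), config = mcmc_config(),
                     free = c("r_flap", "r_tube", "lambda_subordinate",
                              "s_entry", "g_general", "g_box",
                              "g_specific", "rho"),
                     init_params = NULL, data = NULL) {
  if (is.null(data)) data <- prepare_likelihood_data(log, variant)
  if (is.null(init_params)) init_params <- default_init(data, free)
  d <- length(free)
  transforms <- vapply(free, param_transform, "")
  re_idx <- grep("^(u|v)\\.", free)
  blocks <- if (length(re_idx))
    list(setdiff(seq_len(d), re_idx), re_idx) else list(seq_len(d))

  # make sure every free random effect has a (named) slot to write into
  for (nm in free[grepl("^u\\.", free)]) {
    id <- sub("^u\\.", "", nm)
    if (!id %in% names(init_params$u)) init_params$u[[id]] <- 0
  }
  for (nm in free[grepl("^v\\.", free)]) {
    id <- sub("^v\\.", "", nm)
    if (!id %in% names(init_params$v)) init_params$v[[id]] <- 0
  }
  # precompiled setter plan and prior plan (avoids per-iteration parsing)
  plan <- lapply(free, function(nm) {
    p2 <- set_param(init_params, nm, 0.123456789)
    for (field in names(p2)) {
      hit <- which(p2[[field]] != init_params[[field]])
      if (length(hit)) return(list(field = field, idx = hit))
    }
    stop("cannot locate parameter ", nm, call. = FALSE)
  })
  prior_kind <- vapply(free, function(nm) {
    if (grepl("^r_", nm)) "r"
    else if (grepl("^beta_", nm)) "beta"
    else if (grepl("^(lambda_|s_)", nm)) "unit"
    else if (nm == "gamma") "gamma"
    else if (grepl("^g_", nm)) "g"
    else if (nm == "rho") "rho"
    else if (grepl("^sigma_", nm)) "sigma"
    else if (grepl("^u\\.", nm)) "u"
    else if (grepl("^v\\.", nm)) "v"
    else stop("no prior for ", nm, call. = FALSE)
  }, "")
  hn_scale <- c(r = priors$r_scale, gamma = priors$gamma_scale,
                g = priors$g_scale, rho = priors$rho_scale,
                sigma = priors$sigma_scale)
  is_log <- transforms == "log"
  is_logit <- transforms == "logit"

  build_params <- function(nat) {
    p <- init_params
    for (j in seq_len(d)) p[[plan[[j]]$field]][plan[[j]]$idx] <- nat[j]
    p
  }
  log_prior_fast <- function(nat, p) {
    lp <- 0
    for (j in seq_len(d)) {
      kind <- prior_kind[j]
      lp <- lp + switch(kind,
        unit = 0,  # the logit transform already constrains to (0, 1)
        beta = dnorm(nat[j], 0, priors$beta_sd, log = TRUE),
        u = dnorm(nat[j], 0, max(p$sigma_ind, 1e-6), log = TRUE),
        v = dnorm(nat[j], 0, max(p$sigma_group, 1e-6), log = TRUE),
        log(2) + dnorm(nat[j], 0, hn_scale[[kind]], log = TRUE))
    }
    lp
  }
  log_target <- function(theta) {
    nat <- theta
    nat[is_log] <- exp(theta[is_log])
    nat[is_logit] <- 1 / (1 + exp(-theta[is_logit]))
    if (any(!is.finite(nat))) return(-Inf)
    p <- build_params(nat)
    ll <- smfm_log_likelihood(p, variant = variant, data = data)
    if (!is.finite(ll$loglik)) return(-Inf)
    jac <- sum(theta[is_log]) +
      sum(log(nat[is_logit]) + log1p(-nat[is_logit]))
    ll$loglik + log_prior_fast(nat, p) + jac
  }
  init_theta <- vapply(seq_len(d), function(j)
    from_natural(get_param(init_params, free[j]), transforms[j]), 0.0)

  chains <- vector("list", config$n_chains)
  loglik <- vector("list", config$n_chains)
  accepts <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed((config$seed + 104729L * (ch - 1L)) %% .Machine$integer.max)
    jit <- init_theta + if (ch == 1) 0 else rnorm(d, 0, 0.1)
    # fall back to the unjittered start if the jitter left the support
    lt0 <- log_target(jit)
    if (!is.finite(lt0)) jit <- init_theta
    res <- adaptive_metropolis(log_target, jit, config, blocks)
    nat <- res$draws
    for (j in seq_len(d)) nat[, j] <- to_natural(res$draws[, j], transforms[j])
    colnames(nat) <- free
    colnames(res$draws) <- free
    # per-draw log-likelihood = log target minus prior and Jacobian
    ll_d <- vapply(seq_len(nrow(res$draws)), function(i) {
      th <- res$draws[i, ]
      nat_i <- th
      nat_i[is_log] <- exp(th[is_log])
      nat_i[is_logit] <- 1 / (1 + exp(-th[is_logit]))
      p <- build_params(nat_i)
      jac <- sum(th[is_log]) +
        sum(log(nat_i[is_logit]) + log1p(-nat_i[is_logit]))
      res$lt[i] - log_prior_fast(nat_i, p) - jac
    }, 0.0)
    chains[[ch]] <- list(natural = nat, transformed = res$draws)
    loglik[[ch]] <- ll_d
    accepts[[ch]] <- res$acceptance
  }
  structure(list(chains = chains, loglik = loglik, acceptance = accepts,
                 free = free, transforms = transforms,
                 init_params = init_params, variant = variant,
                 priors = priors, config = config, data = data),
            class = "smfm_chains")
}

#' Reasonable starting parameters derived from the data
#'
#' The baseline rate starts at the crude event rate (events per
#' individual-second at risk, split over the four options); learning and
#' social parameters start at small positive values inside their support.
#'
#' @param data a [prepare_likelihood_data()] result.
#' @param free free-parameter names (unused values are left at defaults).
#' @return an [smfm_params()].
#' @export
default_init <- function(data, free = character()) {
  Ttot <- sum(data$seg[, 3] - data$seg[, 2])
  r0 <- max(data$n_events, 1) / max(4 * Ttot, 1)
  smfm_params(r = c(flap = r0, tube = r0),
              sigma_ind = 0.5, sigma_group = 0.5,
              lambda = c(subordinate = 0.02, dominant = 0.02),
              s = c(manipulation = 0.002, entry = 0.002, feeding = 0.002),
              gamma = 1, g_general = 0.5, g_box = 0.5, g_sametype = 0.01,
              g_specific = 0.5, rho = 0.05)
}

#' @export
print.smfm_chains <- function(x, ...) {
  n <- sum(vapply(x$chains, function(c) nrow(c$natural), 0L))
  cat(sprintf("<smfm_chains> %d chains, %d kept draws, %d free parameters\n",
              length(x$chains), n, length(x$free)))
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

pooled_draws <- function(chains, scale = c("natural", "transformed")) {
  scale <- match.arg(scale)
  do.call(rbind, lapply(chains$chains, `[[`, scale))
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws (exact shortest-window scan).
#'
#' @param draws numeric sample (at least 100 draws).
#' @param mass probability mass, in (0, 1).
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 100) stop("too few draws for an HPD interval (need >= 100)",
                    call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must lie in (0, 1)", call. = FALSE)
  x <- sort(draws)
  m <- ceiling(mass * n)
  i <- seq_len(n - m + 1)
  w <- x[i + m - 1] - x[i]
  j <- which.min(w)
  c(lower = x[j], upper = x[j + m - 1])
}

#' Posterior probability of an inequality
#'
#' Fraction of draws of a contrast that fall at or below (or above) a
#' threshold; e.g. `posterior_prob(lam_dom - lam_sub)` is the posterior
#' probability that dominants learn no faster than subordinates.
#'
#' @param draws per-draw values of the contrast.
#' @param threshold reference value (default 0).
#' @param direction `"leq"` (default), `"geq"`, `"lt"` or `"gt"`.
#' @return probability in `[0, 1]`.
#' @export
posterior_prob <- function(draws, threshold = 0,
                           direction = c("leq", "geq", "lt", "gt")) {
  direction <- match.arg(direction)
  if (!length(draws)) stop("empty draws", call. = FALSE)
  switch(direction,
         leq = mean(draws <= threshold),
         geq = mean(draws >= threshold),
         lt = mean(draws < threshold),
         gt = mean(draws > threshold))
}

# effective sample size via Geyer's initial positive sequence
ess_one <- function(x) {
  n <- length(x)
  if (n < 10 || sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2, 500), plot = FALSE,
                    demean = TRUE)$acf[-1]
  # sum pairs while they stay positive
  s <- 0
  for (i in seq(1, length(rho) - 1, by = 2)) {
    pair <- rho[i] + rho[i + 1]
    if (is.na(pair) || pair <= 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

rhat_split <- function(xs) {
  # xs: list of per-chain vectors; split each in half
  halves <- unlist(lapply(xs, function(x) {
    h <- length(x) %/% 2
    list(x[seq_len(h)], x[h + seq_len(h)])
  }), recursive = FALSE)
  m <- length(halves); n <- min(lengths(halves))
  if (n < 4) return(NA_real_)
  halves <- lapply(halves, function(x) x[seq_len(n)])
  means <- vapply(halves, mean, 0.0)
  vars <- vapply(halves, var, 0.0)
  W <- mean(vars); B <- n * var(means)
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Summarize posterior chains
#'
#' Per free parameter: posterior median, 95% HPD interval, effective
#' sample size and split R-hat; optional inequality probabilities for
#' contrasts given as strings naming parameter pairs, e.g.
#' `"lambda_dominant - lambda_subordinate"` (probability that the
#' difference is `<= 0`).  A warning flag is set when R-hat exceeds 1.05
#' or ESS falls below 200 for any parameter.
#'
#' @param chains an [run_mcmc()] result.
#' @param prob HPD mass (default 0.95).
#' @param contrasts character vector of contrast expressions in the free
#'   parameter names.
#' @return an object of class `smfm_posterior_summary`: list with
#'   `parameters` (data.frame), `contrasts` (data.frame or NULL),
#'   `converged` (logical).
#' @export
summarize_posterior <- function(chains, prob = 0.95, contrasts = NULL) {
  nat <- pooled_draws(chains, "natural")
  free <- chains$free
  per_chain <- lapply(chains$chains, `[[`, "natural")
  tab <- do.call(rbind, lapply(seq_along(free), function(j) {
    x <- nat[, j]
    h <- hpd_interval(x, prob)
    data.frame(parameter = free[j], median = median(x),
               hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
               ess = sum(vapply(per_chain, function(m) ess_one(m[, j]), 0.0)),
               rhat = rhat_split(lapply(per_chain, function(m) m[, j])),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  ctab <- NULL
  if (!is.null(contrasts)) {
    env <- as.data.frame(nat)
    # parameter names contain dots for random effects; make syntactic
    names(env) <- make.names(names(env))
    ctab <- do.call(rbind, lapply(contrasts, function(cx) {
      v <- eval(parse(text = make.names_expr(cx)), envir = env)
      h <- hpd_interval(v, prob)
      data.frame(contrast = cx, median = median(v),
                 hpd_lower = h[["lower"]], hpd_upper = h[["upper"]],
                 p_leq_0 = posterior_prob(v), stringsAsFactors = FALSE)
    }))
  }
  converged <- all(tab$rhat < 1.05, na.rm = TRUE) && all(tab$ess > 200)
  if (!converged)
    warning("convergence gating failed (R-hat >= 1.05 or ESS <= 200); ",
            "summaries may be unreliable", call. = FALSE)
  structure(list(parameters = tab, contrasts = ctab, converged = converged),
            class = "smfm_posterior_summary")
}

make.names_expr <- function(x) {
  # random-effect names like u.IND1 are already syntactic; pass through
  x
}

#' @export
print.smfm_posterior_summary <- function(x, ...) {
  cat("<smfm_posterior_summary>", if (!x$converged) " (NOT CONVERGED)", "\n",
      sep = "")
  print(x$parameters, digits = 4)
  if (!is.null(x$contrasts)) print(x$contrasts, digits = 4)
  invisible(x)
}

#' DIC arithmetic from deviance draws
#'
#' `Dbar` is the posterior mean deviance, `pD = Dbar - Dhat` the
#' effective number of parameters (deviance at a posterior point
#' estimate), and `DIC = Dbar + pD`.
#'
#' @param deviance per-draw deviances (`-2 * loglik`).
#' @param deviance_hat deviance at the posterior point estimate.
#' @return list with `DIC`, `Dbar`, `pD`, `negative_pD` flag.
#' @export
dic_components <- function(deviance, deviance_hat) {
  Dbar <- mean(deviance)
  pD <- Dbar - deviance_hat
  if (pD < 0)
    warning("negative pD: posterior mean fits worse than average draw",
            call. = FALSE)
  list(DIC = Dbar + pD, Dbar = Dbar, pD = pD, negative_pD = pD < 0)
}

#' Deviance information criterion of a fitted rate model
#'
#' The deviance point estimate is evaluated at the posterior mean of the
#' *transformed* (unconstrained) parameters, matching common DIC
#' practice; the posterior median is available as an alternative.
#'
#' @param chains an [run_mcmc()] result.
#' @param point `"mean"` (default) or `"median"` of the transformed draws.
#' @return list with `DIC`, `Dbar`, `pD`, `negative_pD`.
#' @export
dic <- function(chains, point = c("mean", "median")) {
  point <- match.arg(point)
  dev <- -2 * unlist(chains$loglik)
  tr <- pooled_draws(chains, "transformed")
  theta_hat <- apply(tr, 2, if (point == "mean") mean else median)
  p <- chains$init_params
  for (j in seq_along(chains$free))
    p <- set_param(p, chains$free[j],
                   to_natural(theta_hat[j], chains$transforms[j]))
  ll_hat <- smfm_log_likelihood(p, variant = chains$variant,
                                data = chains$data)$loglik
  dic_components(dev, -2 * ll_hat)
}

#' Compare model variants by DIC
#'
#' Fits each variant to the same event log with the same sampler settings
#' and free-parameter set and tabulates DIC differences from the first
#' (reference) variant.  Runs whose R-hat exceeds 1.05 are flagged.
#'
#' @param log a validated [event_log()].
#' @param variants named list of [smfm_variant()]s; the first is the
#'   reference.
#' @param priors,config,free,init_params passed to [run_mcmc()].
#' @return data.frame with one row per variant: `DIC`, `Dbar`, `pD`,
#'   `dDIC`, `mc_se_dbar` (Monte-Carlo SE of the mean deviance),
#'   `max_rhat`, `flagged`.
#' @export
compare_variants <- function(log, variants, priors = prior_spec(),
                             config = mcmc_config(),
                             free = c("r_flap", "r_tube",
                                      "lambda_subordinate", "s_entry",
                                      "g_general", "g_box", "g_specific",
                                      "rho"),
                             init_params = NULL) {
  stopifnot(length(variants) >= 2)
  if (is.null(names(variants)))
    names(variants) <- paste0("variant", seq_along(variants))
  rows <- lapply(names(variants), function(nm) {
    v <- variants[[nm]]
    fr <- if (v$transient) free
      else setdiff(free, grep("^g_|^rho$", free, value = TRUE))
    ch <- run_mcmc(log, variant = v, priors = priors, config = config,
                   free = fr, init_params = init_params)
    dd <- dic(ch)
    sm <- suppressWarnings(summarize_posterior(ch))
    dev <- -2 * unlist(ch$loglik)
    ess_dev <- max(1, ess_one(dev))
    data.frame(variant = nm, DIC = dd$DIC, Dbar = dd$Dbar, pD = dd$pD,
               mc_se_dbar = sd(dev) / sqrt(ess_dev),
               max_rhat = max(sm$parameters$rhat, na.rm = TRUE),
               flagged = !sm$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$dDIC <- out$DIC - out$DIC[1]
  out
}
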