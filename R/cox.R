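#' Default candidate covariates for the bout-outcome Cox models
#'
#' Counts of prior successes and failures at the manipulated and the
#' other option-type, the solved-ever flag, counts of observed feeding
#' successes per option-type, and the transient recency term
#' `exp(-rho * dt)` for the time since another individual last interacted
#' with the same option at the same box.
#' @export
DEFAULT_COX_COVARIATES <- c("succ_same", "succ_other", "fail_same",
                            "fail_other", "solved_ever_same",
                            "obs_feed_same", "obs_feed_other", "recency")

#' Build the per-bout table for a Cox analysis of solving or abandonment
#'
#' One record per non-demonstrator bout at the modelled options.  For the
#' solving analysis the event is a solved bout and abandoned bouts are
#' censored; for the abandonment analysis the roles are reversed.  All
#' covariates are frozen at bout start (experience strictly prior to it).
#'
#' The transient covariate `recency` encodes the time since another
#' individual last interacted with the same option at the same box as
#' `exp(-rho * dt)` (1 if such a bout is ongoing at bout start, 0 if it
#' has never happened this session), with `rho` typically taken from a
#' rate-model fit.
#'
#' @param log a validated [event_log()].
#' @param exp the matching [build_experience_timeline()] result (built
#'   from `log` if omitted).
#' @param outcome `"solving"` or `"abandonment"`.
#' @param rho decay rate for the `recency` covariate (1/seconds).
#' @return data.frame of class `smfm_bout_table` with columns `bout_id`,
#'   `individual_id`, `group_id`, `age_class`, `sex`, `dominance`,
#'   `option_type`, `box_side`, `duration`, `event` (logical), plus the
#'   covariates in [DEFAULT_COX_COVARIATES].
#' @export
build_bout_table <- function(log, exp = NULL,
                             outcome = c("solving", "abandonment"),
                             rho = log(2) / 20) {
  outcome <- match.arg(outcome)
  if (is.null(exp)) exp <- build_experience_timeline(log)
  ind <- log$individuals
  bt <- log$bouts
  keep <- bt$option_type %in% OPTION_TYPES &
    !ind$is_demonstrator[match(bt$individual_id, ind$id)]
  bt <- bt[keep, , drop = FALSE]
  if (!nrow(bt)) stop("no analysable bouts", call. = FALSE)
  rows <- lapply(seq_len(nrow(bt)), function(i) {
    b <- bt[i, ]
    k <- match(b$option_type, OPTION_TYPES); ko <- 3 - k
    cnt <- experience_counts(exp, b$individual_id, b$session_id, b$t_start)
    # time since another individual last interacted at the same (k, l)
    oth <- log$bouts[log$bouts$session_id == b$session_id &
                       log$bouts$individual_id != b$individual_id &
                       log$bouts$option_type == b$option_type &
                       log$bouts$box_side == b$box_side, , drop = FALSE]
    rec <- 0
    if (nrow(oth)) {
      if (any(oth$t_start < b$t_start & oth$t_end >= b$t_start)) rec <- 1
      else {
        prior <- oth$t_end[oth$t_end < b$t_start]
        if (length(prior)) rec <- exp(-rho * (b$t_start - max(prior)))
      }
    }
    ir <- ind[ind$id == b$individual_id, ]
    data.frame(
      bout_id = b$bout_id, individual_id = b$individual_id,
      group_id = ir$group_id, age_class = ir$age_class, sex = ir$sex,
      dominance = ir$dominance, option_type = b$option_type,
      box_side = b$box_side,
      duration = b$t_end - b$t_start,
      event = if (outcome == "solving") b$outcome == "solved"
              else b$outcome == "abandoned",
      succ_same = unname(cnt$R[k]), succ_other = unname(cnt$R[ko]),
      fail_same = unname(cnt$F[k]), fail_other = unname(cnt$F[ko]),
      solved_ever_same = as.numeric(cnt$solved_ever[k]),
      obs_feed_same = unname(cnt$O["feeding", k]),
      obs_feed_other = unname(cnt$O["feeding", ko]),
      recency = rec, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (any(out$duration <= 0)) stop("zero-duration bout", call. = FALSE)
  attr(out, "outcome") <- outcome
  attr(out, "rho") <- rho
  class(out) <- c("smfm_bout_table", "data.frame")
  out
}

cox_design <- function(records, covariates) {
  X <- as.matrix(as.data.frame(lapply(records[covariates], as.numeric)))
  colnames(X) <- covariates
  X
}

# Efron/Breslow partial log-likelihood with analytic gradient and Hessian
cox_pll_core <- function(time, event, X, beta, ties = "efron") {
  n <- length(time); p <- ncol(X)
  ord <- order(time, -as.integer(event))
  time <- time[ord]; event <- event[ord]; X <- X[ord, , drop = FALSE]
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0; grad <- numeric(p); hess <- matrix(0, p, p)
  # reverse-cumulative risk-set sums
  ut <- unique(time[event])
  if (!length(ut)) stop("no events in the data", call. = FALSE)
  for (t0 in ut) {
    risk <- which(time >= t0)
    D <- which(time == t0 & event)
    d <- length(D)
    wr <- w[risk]; Xr <- X[risk, , drop = FALSE]
    S0 <- sum(wr)
    S1 <- drop(crossprod(Xr, wr))
    S2 <- crossprod(Xr * wr, Xr)
    wd <- w[D]; Xd <- X[D, , drop = FALSE]
    S0d <- sum(wd)
    S1d <- drop(crossprod(Xd, wd))
    S2d <- crossprod(Xd * wd, Xd)
    ll <- ll + sum(eta[D])
    for (r in seq_len(d) - 1L) {
      f <- if (ties == "efron") r / d else 0
      den <- S0 - f * S0d
      m1 <- (S1 - f * S1d) / den
      m2 <- (S2 - f * S2d) / den
      ll <- ll - log(den)
      grad <- grad - m1
      hess <- hess - (m2 - tcrossprod(m1))
    }
    grad <- grad + colSums(Xd)
  }
  list(loglik = ll, gradient = grad, hessian = hess)
}

#' Cox partial log-likelihood
#'
#' Partial log-likelihood of a proportional-hazards model at given
#' coefficients, with the Efron approximation for tied event times
#' (Breslow available).
#'
#' @param records an [build_bout_table()] result, or any data.frame with
#'   `duration`, `event` and covariate columns.
#' @param coefficients named numeric vector; the names select the
#'   covariate columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return the partial log-likelihood (scalar).
#' @export
cox_partial_loglik <- function(records, coefficients,
                               ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (any(records$duration <= 0)) stop("zero durations", call. = FALSE)
  X <- cox_design(records, names(coefficients))
  cox_pll_core(records$duration, as.logical(records$event), X,
               as.numeric(coefficients), ties)$loglik
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the partial likelihood with analytic gradient and Hessian,
#' with step-halving, to a gradient norm below `1e-8`.
#'
#' @param records see [cox_partial_loglik()].
#' @param covariates character vector of covariate columns (may be
#'   empty: the null model).
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `smfm_coxfit`: `coef`, `vcov`, `loglik`,
#'   `loglik_null`, `AIC`, `n`, `n_events`, `converged`.
#' @export
fit_cox <- function(records, covariates = DEFAULT_COX_COVARIATES,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  time <- records$duration; event <- as.logical(records$event)
  if (!any(event)) stop("no events in the data", call. = FALSE)
  p <- length(covariates)
  null_ll <- cox_pll_core(time, event,
                          matrix(0, length(time), 0), numeric(0),
                          ties)$loglik
  if (p == 0) {
    fit <- list(coef = numeric(0), vcov = matrix(0, 0, 0),
                loglik = null_ll, loglik_null = null_ll,
                AIC = -2 * null_ll, n = length(time),
                n_events = sum(event), converged = TRUE, iter = 0L)
    class(fit) <- "smfm_coxfit"
    return(fit)
  }
  X <- cox_design(records, covariates)
  if (qr(X)$rank < p)
    stop("design matrix is rank deficient on covariates: ",
         paste(covariates, collapse = ", "), call. = FALSE)
  beta <- numeric(p)
  core <- cox_pll_core(time, event, X, beta, ties)
  converged <- FALSE
  for (it in seq_len(50)) {
    step <- tryCatch(solve(core$hessian, core$gradient),
                     error = function(e) NULL)
    if (is.null(step)) break
    step <- -step
    ok <- FALSE
    for (h in 0:10) {
      cand <- beta + step / 2^h
      core2 <- tryCatch(cox_pll_core(time, event, X, cand, ties),
                        error = function(e) NULL)
      if (!is.null(core2) && is.finite(core2$loglik) &&
          core2$loglik >= core$loglik - 1e-12) { ok <- TRUE; break }
    }
    if (!ok) break
    beta <- cand; core <- core2
    if (sqrt(sum(core$gradient^2)) < 1e-8) { converged <- TRUE; break }
  }
  vcov <- tryCatch(solve(-core$hessian), error = function(e)
    matrix(NA_real_, p, p))
  fit <- list(coef = setNames(beta, covariates),
              vcov = vcov, loglik = core$loglik, loglik_null = null_ll,
              AIC = -2 * core$loglik + 2 * p, n = length(time),
              n_events = sum(event), converged = converged, iter = it)
  class(fit) <- "smfm_coxfit"
  fit
}

#' @export
print.smfm_coxfit <- function(x, ...) {
  cat(sprintf("<smfm_coxfit> n = %d, events = %d, loglik = %.4f, AIC = %.2f%s\n",
              x$n, x$n_events, x$loglik, x$AIC,
              if (x$converged) "" else " (NOT CONVERGED)"))
  if (length(x$coef)) {
    se <- sqrt(diag(x$vcov))
    print(data.frame(coef = x$coef, `exp(coef)` = exp(x$coef), se = se,
                     check.names = FALSE), digits = 4)
  }
  invisible(x)
}

#' Akaike weights from a vector of AIC values
#' @param aic numeric AIC values.
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' All-subsets Cox fitting with AIC model averaging
#'
#' Fits every subset of the candidate covariates (including the null
#' model), weights each fit by its Akaike weight, and reports per
#' covariate the total weight (the evidence for the corresponding
#' behavioural mechanism), the model-averaged coefficient (taking 0 in
#' models that omit it), the unconditional standard error of
#' Burnham & Anderson, and the back-transformed hazard multiplier with
#' its 95% unconditional confidence interval.
#'
#' @param records an [build_bout_table()] result.
#' @param candidates candidate covariate columns (at most 20).
#' @param ties `"efron"` or `"breslow"`.
#' @return object of class `smfm_model_average`: data.frame with one row
#'   per candidate (`weight`, `coef_avg`, `se_unconditional`,
#'   `multiplier`, `uci_lower`, `uci_upper`) plus attributes `n_models`
#'   and `model_table`.
#' @export
all_subsets_average <- function(records,
                                candidates = DEFAULT_COX_COVARIATES,
                                ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  k <- length(candidates)
  if (k > 20)
    stop("more than 20 candidate covariates (2^k model set too large); ",
         "reduce the candidate list", call. = FALSE)
  subsets <- lapply(0:(2^k - 1), function(m)
    candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  fits <- lapply(subsets, function(s)
    tryCatch(fit_cox(records, s, ties), error = function(e) NULL))
  keep <- vapply(fits, function(f) !is.null(f) && f$converged, TRUE)
  if (!all(keep))
    warning(sum(!keep), " of ", length(fits),
            " subset fits failed or did not converge and were excluded",
            call. = FALSE)
  fits <- fits[keep]; subsets <- subsets[keep]
  if (!length(fits)) stop("no subset fit converged", call. = FALSE)
  aics <- vapply(fits, `[[`, 0.0, "AIC")
  w <- akaike_weights(aics)
  out <- do.call(rbind, lapply(candidates, function(cv) {
    bin <- vapply(subsets, function(s) cv %in% s, TRUE)
    bet <- vapply(seq_along(fits), function(i)
      if (bin[i]) fits[[i]]$coef[[cv]] else 0, 0.0)
    vr <- vapply(seq_along(fits), function(i)
      if (bin[i]) fits[[i]]$vcov[match(cv, subsets[[i]]),
                                 match(cv, subsets[[i]])] else 0, 0.0)
    b_avg <- sum(w * bet)
    se_u <- sum(w * sqrt(vr + (bet - b_avg)^2))
    data.frame(covariate = cv, weight = sum(w[bin]), coef_avg = b_avg,
               se_unconditional = se_u, multiplier = exp(b_avg),
               uci_lower = exp(b_avg - 1.96 * se_u),
               uci_upper = exp(b_avg + 1.96 * se_u),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_models") <- length(fits)
  attr(out, "model_table") <- data.frame(
    model = vapply(subsets, function(s)
      if (length(s)) paste(s, collapse = "+") else "(null)", ""),
    AIC = aics, weight = w, stringsAsFactors = FALSE)
  class(out) <- c("smfm_model_average", "data.frame")
  out
}
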