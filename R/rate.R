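#' Rescorla-Wagner association strength from experience counts
#'
#' The count-based closed form of the Rescorla-Wagner recursion, extended
#' with the direct (permanent) effects of observation:
#' `A = 1 - (1 - lambda)^R * prod((1 - s_c)^O_c)` over observation classes
#' `c`.  `A` is the association of an option-type with reward, rises from 0
#' towards 1 with every reward and qualifying observation, and multiplies
#' the interaction rate through `1 + gamma * A`.
#'
#' @param R number of rewarded manipulations (count, `>= 0`).
#' @param O named counts of observations per class (`manipulation`,
#'   `entry`, `feeding`; missing classes count 0).  Classes are nested:
#'   supply cumulative counts.
#' @param lambda asocial learning rate in `[0, 1)`.
#' @param s named social learning rates per class, each in `[0, 1)`.
#' @return association strength in `[0, 1)`; vectorized over `R`.
#' @export
association_strength <- function(R, O = c(manipulation = 0, entry = 0,
                                          feeding = 0),
                                 lambda, s = c(manipulation = 0, entry = 0,
                                               feeding = 0)) {
  if (any(lambda < 0 | lambda >= 1) || any(s < 0 | s >= 1))
    stop("learning rates must lie in [0, 1)", call. = FALSE)
  if (any(R < 0) || any(O < 0)) stop("counts must be >= 0", call. = FALSE)
  O_full <- setNames(numeric(3), OBS_CLASSES)
  O_full[names(O)[names(O) %in% OBS_CLASSES]] <-
    O[names(O) %in% OBS_CLASSES]
  s_full <- setNames(numeric(3), OBS_CLASSES)
  s_full[names(s)[names(s) %in% OBS_CLASSES]] <-
    s[names(s) %in% OBS_CLASSES]
  1 - (1 - lambda)^R * prod((1 - s_full)^O_full)
}

# strengths for one age group as a plain list
strengths_for_age <- function(params, age_class) {
  grp <- as.character(transient_age_group(age_class))
  list(g_general = unname(params$g_general[grp]),
       g_box = unname(params$g_box[grp]),
       g_sametype = unname(params$g_sametype[grp]),
       g_specific = unname(params$g_specific[grp]))
}

#' Transient social-enhancement addend at a time point
#'
#' Evaluates the exponentially decaying social kernels for all four
#' (option-type, box) pairs given the times of the most recent qualifying
#' observations.  Each pair receives `g_general * exp(-rho * (t - tau_any))
#' + g_box * exp(-rho * (t - tau_box)) + g_sametype * exp(-rho * (t -
#' tau_type)) + g_specific * exp(-rho * (t - tau_kl))`, where `tau_any`,
#' `tau_box`, `tau_type` are the most recent observations anywhere, on the
#' same box, and of the same option-type, and a term is 0 when no
#' qualifying observation has occurred this session.  Every term halves
#' each `log(2)/rho` seconds.
#'
#' @param t evaluation time (session-local seconds), `>=` every `tau`.
#' @param tau 2 x 2 matrix (option-type x box) of most recent qualifying
#'   observation times, `NA` where none (see [last_observation_times()]).
#' @param strengths list with elements `g_general`, `g_box`, `g_sametype`,
#'   `g_specific` (scalars), or an [smfm_params()] (combined with
#'   `age_class`).
#' @param rho decay rate, 1/seconds, `> 0`.
#' @param age_class age class used to pick strengths when `strengths` is
#'   an `smfm_params`.
#' @return 2 x 2 matrix of dimensionless addends (`>= 0`).
#' @export
transient_addend <- function(t, tau, strengths, rho = NULL,
                             age_class = "adult") {
  if (inherits(strengths, "smfm_params")) {
    if (is.null(rho)) rho <- strengths$rho
    strengths <- strengths_for_age(strengths, age_class)
  }
  if (is.null(rho) || rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (any(t < tau, na.rm = TRUE))
    stop("t must not be earlier than any tau", call. = FALSE)
  decay <- function(tt) ifelse(is.na(tt), 0, exp(-rho * (t - tt)))
  out <- matrix(0, 2, 2, dimnames = dimnames(tau))
  tau_any <- if (all(is.na(tau))) NA_real_ else max(tau, na.rm = TRUE)
  for (k in 1:2) for (l in 1:2) {
    tau_box <- if (all(is.na(tau[, l]))) NA_real_ else max(tau[, l], na.rm = TRUE)
    tau_type <- if (all(is.na(tau[k, ]))) NA_real_ else max(tau[k, ], na.rm = TRUE)
    out[k, l] <- strengths$g_general * decay(tau_any) +
      strengths$g_box * decay(tau_box) +
      strengths$g_sametype * decay(tau_type) +
      strengths$g_specific * decay(tau[k, l])
  }
  out
}

resolve_k <- function(k) if (is.character(k)) match(k, OPTION_TYPES) else as.integer(k)
resolve_l <- function(l) if (is.character(l)) match(l, BOX_SIDES) else as.integer(l)

# linear predictor of the time-constant covariates plus random effects
linear_predictor <- function(params, ind_row) {
  x <- c(age_pup = as.numeric(ind_row$age_class == "pup"),
         age_juvenile = as.numeric(ind_row$age_class == "juvenile"),
         age_subadult = as.numeric(ind_row$age_class == "subadult"),
         sexM = as.numeric(ind_row$sex == "M"),
         dominant = as.numeric(ind_row$dominance == "dominant"))
  b <- setNames(numeric(5), names(x))
  b[names(params$beta)[names(params$beta) %in% names(b)]] <-
    params$beta[names(params$beta) %in% names(b)]
  u <- if (ind_row$id %in% names(params$u)) params$u[[ind_row$id]] else 0
  v <- if (ind_row$group_id %in% names(params$v)) params$v[[ind_row$group_id]] else 0
  sum(b * x) + u + v
}

# sorted qualifying tau event times per (k, l) for one individual-session
tau_time_sets <- function(exp, log, individual_id, session_id, condition) {
  ev <- tau_events(exp, log, individual_id, session_id, condition)
  sets <- vector("list", 4)  # index (l - 1) * 2 + k
  for (k in 1:2) for (l in 1:2)
    sets[[(l - 1) * 2 + k]] <- sort(ev$t_end[ev$k == k & ev$l == l])
  sets
}

last_before <- function(times, t) {
  # latest element of sorted `times` strictly before each t, NA if none
  idx <- findInterval(t, times, left.open = TRUE)
  out <- rep(NA_real_, length(t))
  out[idx > 0] <- times[idx[idx > 0]]
  out
}

#' Instantaneous rate of bout initiation under the rate model
#'
#' Evaluates the modelled rate at which an individual initiates bouts of
#' interaction with option-type `k` on box `l` at session time(s) `t`:
#' baseline rate, times the exponential of the covariate linear predictor
#' and random effects, times the learning/transient multiplier
#' (`1 + gamma * A + T` by default).  Vectorized over `t`.
#'
#' @param exp an [build_experience_timeline()] result.
#' @param individual_id,session_id ids.
#' @param k option-type (`"flap"`/`"tube"` or 1/2).
#' @param l box (`"left"`/`"right"` or 1/2).
#' @param t session-local time(s), seconds.
#' @param params an [smfm_params()].
#' @param variant an [smfm_variant()].
#' @param log the originating event log (needed for
#'   `tau_condition = "all_present"`).
#' @param decompose if `TRUE` return a data.frame with columns `baseline`,
#'   `learning_multiplier`, `transient_addend`, `total` instead of the
#'   rate vector.
#' @return numeric vector of rates (events/second), or the decomposition.
#' @export
interaction_rate <- function(exp, individual_id, session_id, k, l, t,
                             params, variant = smfm_variant(), log = NULL,
                             decompose = FALSE) {
  validate_smfm_params(params)
  k <- resolve_k(k); l <- resolve_l(l)
  if (is.na(k) || is.na(l)) stop("undefined option or box", call. = FALSE)
  ind_row <- exp$individuals[exp$individuals$id == individual_id, ]
  if (!nrow(ind_row)) stop("unknown individual: ", individual_id, call. = FALSE)
  lp <- linear_predictor(params, ind_row)
  lambda <- params$lambda[[ind_row$dominance]]
  st <- strengths_for_age(params, ind_row$age_class)

  # counts as step functions of t (strictly-before semantics)
  g <- global_time(exp, session_id, t)
  ow <- exp$own
  ow <- ow[ow$individual_id == individual_id &
             same_group(exp, ow$session_id, session_id), ]
  Rt <- findInterval(g, sort(ow$t_end_global[ow$k == k & ow$rewarded]),
                     left.open = TRUE)
  sn <- exp$seen
  sn <- sn[sn$individual_id == individual_id &
             same_group(exp, sn$session_id, session_id), ]
  sk <- sn[sn$k == k, ]
  Om <- findInterval(g, sort(sk$t_end_global), left.open = TRUE)
  Oe <- findInterval(g, sort(sk$t_end_global[sk$saw_entry]), left.open = TRUE)
  Of <- findInterval(g, sort(sk$t_end_global[sk$saw_feeding]), left.open = TRUE)
  A <- 1 - (1 - lambda)^Rt * (1 - params$s[["manipulation"]])^Om *
    (1 - params$s[["entry"]])^Oe * (1 - params$s[["feeding"]])^Of

  Tadd <- numeric(length(t))
  if (variant$transient) {
    sets <- tau_time_sets(exp, log, individual_id, session_id,
                          variant$tau_condition)
    dec <- function(times) {
      tau <- last_before(times, t)
      ifelse(is.na(tau), 0, exp(-params$rho * (t - tau)))
    }
    Tadd <- st$g_general * dec(sort(unlist(sets))) +
      st$g_box * dec(sets[[(l - 1) * 2 + 1]] |> c(sets[[(l - 1) * 2 + 2]]) |> sort()) +
      st$g_sametype * dec(sort(c(sets[[k]], sets[[2 + k]]))) +
      st$g_specific * dec(sets[[(l - 1) * 2 + k]])
  }
  baseline <- unname(params$r[k]) * exp(lp)
  learn <- 1 + params$gamma * A
  total <- if (variant$composition == "additive")
    baseline * (learn + Tadd) else baseline * learn * (1 + Tadd)
  if (decompose)
    data.frame(baseline = baseline, learning_multiplier = learn,
               transient_addend = Tadd, total = total)
  else total
}

#' Exact integrated hazard over a piecewise-constant-state segment
#'
#' Integrates the interaction rate in closed form over `[t0, t1]`,
#' assuming no event inside the open interval changes the individual's
#' experience state or at-risk status (checked; violation is an error).
#' The learning multiplier is constant on the segment and the transient
#' kernels integrate analytically:
#' `integral g * exp(-rho (t - tau)) dt = (g/rho) * (exp(-rho (t0 - tau)) -
#' exp(-rho (t1 - tau)))`.
#'
#' @inheritParams interaction_rate
#' @param t0,t1 segment end points, session-local seconds, `t0 <= t1`.
#' @return the integrated hazard (dimensionless).
#' @export
segment_integrated_hazard <- function(exp, individual_id, session_id, k, l,
                                      t0, t1, params,
                                      variant = smfm_variant(),
                                      log = NULL) {
  if (t1 < t0) stop("t1 must be >= t0", call. = FALSE)
  if (t1 == t0) return(0)
  k <- resolve_k(k); l <- resolve_l(l)
  ind_row <- exp$individuals[exp$individuals$id == individual_id, ]
  # contract: no state change strictly inside the segment
  ow <- exp$own
  ow <- ow[ow$individual_id == individual_id &
             same_group(exp, ow$session_id, session_id), ]
  g0 <- global_time(exp, session_id, t0); g1 <- global_time(exp, session_id, t1)
  sn <- exp$seen
  sn <- sn[sn$individual_id == individual_id &
             same_group(exp, sn$session_id, session_id), ]
  tev <- tau_events(exp, log, individual_id, session_id,
                    variant$tau_condition)
  if (any(ow$t_end_global > g0 & ow$t_end_global < g1) ||
      any(sn$t_end_global > g0 & sn$t_end_global < g1) ||
      any(tev$t_end > t0 & tev$t_end < t1))
    stop("segment spans a state change (contract violation)", call. = FALSE)

  tmid <- t0 + (t1 - t0) / 2
  dc <- interaction_rate(exp, individual_id, session_id, k, l, t0 + (t1 - t0) * 1e-9,
                         params, variant, log, decompose = TRUE)
  baseline <- dc$baseline; learn <- dc$learning_multiplier
  # analytic kernel integrals
  Tint <- 0
  if (variant$transient) {
    st <- strengths_for_age(params, ind_row$age_class)
    sets <- tau_time_sets(exp, log, individual_id, session_id,
                          variant$tau_condition)
    piece <- function(times, gg) {
      tau <- last_before(times, tmid)
      if (is.na(tau) || gg == 0) return(0)
      (gg / params$rho) * (exp(-params$rho * (t0 - tau)) -
                             exp(-params$rho * (t1 - tau)))
    }
    Tint <- piece(sort(unlist(sets)), st$g_general) +
      piece(sort(c(sets[[(l - 1) * 2 + 1]], sets[[(l - 1) * 2 + 2]])), st$g_box) +
      piece(sort(c(sets[[k]], sets[[2 + k]])), st$g_sametype) +
      piece(sets[[(l - 1) * 2 + k]], st$g_specific)
  }
  if (variant$composition == "additive")
    baseline * (learn * (t1 - t0) + Tint)
  else
    baseline * learn * ((t1 - t0) + Tint)
}

#' Specificity of the transient social effect
#'
#' The probability that a naive observer (association `A = 0`) interacts
#' with the same option-type it has just observed, given that it initiates
#' a bout at one of the four options immediately after the observation.
#' Computed from the rate decomposition at `dt = 0`: the observed option
#' carries all four kernels, the same box's other option the general + box
#' kernels, the same option-type on the other box the general + sametype
#' kernels, and the remaining option the general kernel only.
#'
#' @param params an [smfm_params()].
#' @param age_class age class of the observer.
#' @param observed the observed option as `c(option_type, box)`.
#' @return probability in `[0, 1]`.
#' @export
specificity <- function(params, age_class = "adult",
                        observed = c("flap", "left")) {
  ks <- resolve_k(observed[1]); ls <- resolve_l(observed[2])
  st <- strengths_for_age(params, age_class)
  rate <- matrix(0, 2, 2)
  for (k in 1:2) for (l in 1:2) {
    Tkl <- st$g_general +
      (if (l == ls) st$g_box else 0) +
      (if (k == ks) st$g_sametype else 0) +
      (if (k == ks && l == ls) st$g_specific else 0)
    rate[k, l] <- unname(params$r[k]) * (1 + Tkl)
  }
  sum(rate[ks, ]) / sum(rate)
}
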