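#' Parameter set of the stochastic mechanism-fitting rate model
#'
#' Collects every parameter of the interaction-rate model: baseline rates
#' per option-type, log-linear effects of time-constant covariates,
#' individual- and group-level random effects, Rescorla-Wagner asocial
#' learning rates per dominance class, social learning rates per
#' observation class, the relative influence of learning, transient
#' social-enhancement strengths per age group, and the shared exponential
#' decay rate of the transient effects.
#'
#' Transient strengths are dimensionless multiples of the baseline rate
#' and may differ between adults, juveniles/sub-adults and pups.  A scalar
#' supplied for any `g_*` argument is recycled across the three age
#' groups.  `g_sametype` is an optional fourth kernel attached to the most
#' recent observation of the same option-type on either box; with it at 0
#' the three-kernel (general / box / specific) model is recovered exactly,
#' and a positive value is the stimulus-enhancement (SODB > DODB) signal.
#'
#' @param r baseline initiation rates, events/second, named `flap`,`tube`.
#' @param beta named coefficients of the time-constant covariates
#'   (`age_pup`, `age_juvenile`, `age_subadult`, `sexM`, `dominant`;
#'   reference level: adult subordinate female).
#' @param sigma_ind,sigma_group standard deviations of the individual- and
#'   group-level random effects (log scale), `>= 0`.
#' @param u,v named individual / group random-effect values (log scale);
#'   empty vectors mean "all zero".
#' @param lambda asocial learning rate per dominance class, each in
#'   `[0, 1)`, named `subordinate`, `dominant`.
#' @param s social learning rate per observation class, each in `[0, 1)`,
#'   named `manipulation`, `entry`, `feeding`.
#' @param gamma relative influence of learning, `>= 0`.
#' @param g_general,g_box,g_sametype,g_specific transient strengths per age
#'   group (`adult`, `juv_subadult`, `pup`), each `>= 0`.
#' @param rho decay rate of the transient effects, 1/seconds, `> 0`;
#'   `log(2)/rho` is their half-life.
#' @return an object of class `smfm_params`.
#' @seealso [half_life()], [kernel_contrasts()], [interaction_rate()]
#' @export
smfm_params <- function(r = c(flap = 1e-4, tube = 1e-4),
                        beta = c(age_pup = 0, age_juvenile = 0,
                                 age_subadult = 0, sexM = 0, dominant = 0),
                        sigma_ind = 0, sigma_group = 0,
                        u = numeric(), v = numeric(),
                        lambda = c(subordinate = 0, dominant = 0),
                        s = c(manipulation = 0, entry = 0, feeding = 0),
                        gamma = 1,
                        g_general = 0, g_box = 0, g_sametype = 0,
                        g_specific = 0,
                        rho = log(2) / 20) {
  expand_g <- function(g, nm) {
    if (length(g) == 1L && is.null(names(g)))
      g <- setNames(rep(as.numeric(g), 3), TRANSIENT_AGE_GROUPS)
    if (!all(TRANSIENT_AGE_GROUPS %in% names(g)))
      stop(nm, " must be a scalar or named over ",
           paste(TRANSIENT_AGE_GROUPS, collapse = ", "), call. = FALSE)
    g[TRANSIENT_AGE_GROUPS]
  }
  p <- structure(list(
    r = r[OPTION_TYPES], beta = beta, sigma_ind = sigma_ind,
    sigma_group = sigma_group, u = u, v = v,
    lambda = lambda[DOMINANCE], s = s[OBS_CLASSES], gamma = gamma,
    g_general = expand_g(g_general, "g_general"),
    g_box = expand_g(g_box, "g_box"),
    g_sametype = expand_g(g_sametype, "g_sametype"),
    g_specific = expand_g(g_specific, "g_specific"),
    rho = rho), class = "smfm_params")
  validate_smfm_params(p)
  p
}

#' Check an `smfm_params` object against its domain constraints
#' @param p an `smfm_params`.
#' @param stop_on_error if `FALSE`, return `FALSE` instead of stopping.
#' @return `TRUE` (invisibly) if valid.
#' @export
validate_smfm_params <- function(p, stop_on_error = TRUE) {
  bad <- function(msg) {
    if (stop_on_error) stop("invalid smfm_params: ", msg, call. = FALSE)
    FALSE
  }
  if (any(!is.finite(unlist(p[c("r", "beta", "lambda", "s", "gamma",
                                "g_general", "g_box", "g_sametype",
                                "g_specific", "rho", "sigma_ind",
                                "sigma_group")]))))
    return(bad("non-finite value"))
  if (any(p$r <= 0)) return(bad("baseline rates must be > 0"))
  if (any(p$lambda < 0 | p$lambda >= 1))
    return(bad("lambda must lie in [0, 1)"))
  if (any(p$s < 0 | p$s >= 1)) return(bad("s must lie in [0, 1)"))
  if (p$gamma < 0) return(bad("gamma must be >= 0"))
  if (any(c(p$g_general, p$g_box, p$g_sametype, p$g_specific) < 0))
    return(bad("transient strengths must be >= 0"))
  if (p$rho <= 0) return(bad("rho must be > 0"))
  if (p$sigma_ind < 0 || p$sigma_group < 0)
    return(bad("random-effect SDs must be >= 0"))
  invisible(TRUE)
}

#' @export
print.smfm_params <- function(x, ...) {
  cat("<smfm_params>\n")
  cat(sprintf("  baseline r: flap %.3g, tube %.3g /s; gamma %.3g\n",
              x$r[1], x$r[2], x$gamma))
  cat(sprintf("  lambda: sub %.3g, dom %.3g; s: manip %.3g, entry %.3g, feed %.3g\n",
              x$lambda[["subordinate"]], x$lambda[["dominant"]],
              x$s[1], x$s[2], x$s[3]))
  cat(sprintf("  transients (adult): general %.3g, box %.3g, sametype %.3g, specific %.3g\n",
              x$g_general[1], x$g_box[1], x$g_sametype[1], x$g_specific[1]))
  cat(sprintf("  rho %.4g /s (half-life %.3g s)\n", x$rho, half_life(x$rho)))
  invisible(x)
}

#' Model-variant flags for the rate model
#'
#' @param tau_condition which observation class triggers/refreshes the
#'   transient effects: any observed manipulation (default), only
#'   observations where box entry was seen, only observations where
#'   feeding was seen, or every bout by another attendee regardless of
#'   observation (`"all_present"`).  These are the condition variants
#'   compared by DIC.
#' @param transient if `FALSE` the transient kernels are dropped entirely
#'   (strengths forced to zero in the likelihood).
#' @param composition how the transient term combines with the learning
#'   multiplier: `"additive"` (default), rate = base * (1 + gamma*A + T),
#'   or `"multiplicative"`, rate = base * (1 + gamma*A) * (1 + T).
#' @return an object of class `smfm_variant`.
#' @export
smfm_variant <- function(tau_condition = c("manipulation", "entry",
                                           "feeding", "all_present"),
                         transient = TRUE,
                         composition = c("additive", "multiplicative")) {
  structure(list(tau_condition = match.arg(tau_condition),
                 transient = isTRUE(transient),
                 composition = match.arg(composition)),
            class = "smfm_variant")
}

#' Half-life of the transient social effects
#'
#' The transient enhancement decays as `exp(-rho * dt)`; its half-life is
#' `log(2) / rho` seconds.
#'
#' @param rho decay rate (1/seconds, `> 0`) or an `smfm_params` object.
#' @return half-life in seconds.
#' @export
half_life <- function(rho) {
  if (inherits(rho, "smfm_params")) rho <- rho$rho
  if (any(rho <= 0)) stop("rho must be > 0", call. = FALSE)
  log(2) / rho
}

#' Raw transient contrasts implied by the hierarchical kernels
#'
#' Converts the hierarchical (general / box / sametype / specific)
#' strengths to the four raw same/different option-type x same/different
#' box effects at the moment of observation: SOSB = general + box +
#' sametype + specific, SODB = general + sametype, DOSB = general + box,
#' DODB = general.  Stimulus enhancement corresponds to SODB > DODB.
#'
#' @param params an `smfm_params`.
#' @return 3 x 4 matrix (age groups x SOSB/SODB/DOSB/DODB).
#' @export
kernel_contrasts <- function(params) {
  m <- cbind(SOSB = params$g_general + params$g_box + params$g_sametype +
               params$g_specific,
             SODB = params$g_general + params$g_sametype,
             DOSB = params$g_general + params$g_box,
             DODB = params$g_general)
  rownames(m) <- TRANSIENT_AGE_GROUPS
  m
}

#' Serialize parameters to a plain list (for JSON config files)
#' @param params an `smfm_params`.
#' @return a named list of numeric vectors.
#' @export
params_to_list <- function(params) {
  lapply(unclass(params), function(x) {
    if (length(x)) as.list(setNames(as.numeric(x), names(x))) else list()
  })
}

#' Rebuild parameters from a plain list (inverse of [params_to_list()])
#' @param x a list as produced by [params_to_list()].
#' @return an `smfm_params`.
#' @export
params_from_list <- function(x) {
  unl <- function(e) if (length(e)) unlist(e) else numeric()
  smfm_params(r = unl(x$r), beta = unl(x$beta),
              sigma_ind = x$sigma_ind[[1]] %||% 0,
              sigma_group = x$sigma_group[[1]] %||% 0,
              u = unl(x$u), v = unl(x$v),
              lambda = unl(x$lambda), s = unl(x$s),
              gamma = x$gamma[[1]] %||% 1,
              g_general = unl(x$g_general), g_box = unl(x$g_box),
              g_sametype = unl(x$g_sametype),
              g_specific = unl(x$g_specific),
              rho = x$rho[[1]])
}
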