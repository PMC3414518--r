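#' Precompile an event log into likelihood segments
#'
#' The log-likelihood of the rate model is a sum over piecewise-constant
#' segments of each non-demonstrator's at-risk time (attending a session,
#' not mid-bout), with segment boundaries wherever the individual's
#' experience state changes (own bout ends, observation ends, qualifying
#' transient-clock events) and an initiation event wherever one of its
#' bouts starts.  This step is parameter-free and can be reused across
#' likelihood evaluations (e.g. throughout an MCMC run).
#'
#' @param log a validated [event_log()].
#' @param variant an [smfm_variant()]; the `tau_condition` determines the
#'   qualifying transient-clock events.
#' @return an object of class `smfm_likelihood_data`.
#' @export
prepare_likelihood_data <- function(log, variant = smfm_variant()) {
  validate_event_log(log)
  exp <- build_experience_timeline(log)
  ind <- log$individuals
  fit_ind <- ind[!ind$is_demonstrator, , drop = FALSE]
  if (!nrow(fit_ind)) stop("no non-demonstrator individuals", call. = FALSE)
  ses <- exp$sessions
  att <- setNames(split_attendees(ses$attendees), ses$session_id)

  # per fitted individual: sorted global times of experience increments
  own <- exp$own; seen <- exp$seen
  segs <- vector("list", nrow(fit_ind) * nrow(ses))
  si <- 0L
  for (ii in seq_len(nrow(fit_ind))) {
    id <- fit_ind$id[ii]
    ow <- own[own$individual_id == id, ]
    sn <- seen[seen$individual_id == id, ]
    rew <- lapply(1:2, function(k)
      sort(ow$t_end_global[ow$k == k & ow$rewarded]))
    om <- lapply(1:2, function(k) sort(sn$t_end_global[sn$k == k]))
    oe <- lapply(1:2, function(k)
      sort(sn$t_end_global[sn$k == k & sn$saw_entry]))
    of <- lapply(1:2, function(k)
      sort(sn$t_end_global[sn$k == k & sn$saw_feeding]))
    grp <- fit_ind$group_id[ii]
    for (sj in which(ses$group_id == grp)) {
      sid <- ses$session_id[sj]
      if (!id %in% att[[sid]]) next
      st <- ses$start_time[sj]; en <- ses$end_time[sj]
      off <- ses$offset[sj]
      loc2glob <- function(t) off + (t - st)

      bts <- log$bouts[log$bouts$session_id == sid &
                         log$bouts$individual_id == id, , drop = FALSE]
      bts <- bts[order(bts$t_start), , drop = FALSE]
      # at-risk intervals: session window minus own bouts; each bout start
      # terminates an at-risk interval, with an event if the bout is at
      # one of the four modelled options
      starts <- c(st, bts$t_end)
      ends <- c(bts$t_start, en)
      evc <- c(ifelse(bts$option_type %in% OPTION_TYPES,
                      (match(bts$box_side, BOX_SIDES) - 1) * 2 +
                        match(bts$option_type, OPTION_TYPES), 0), 0)

      tev <- tau_events(exp, log, id, sid, variant$tau_condition)
      tsets <- lapply(1:4, function(j) {
        k <- (j - 1) %% 2 + 1; l <- (j - 1) %/% 2 + 1
        sort(tev$t_end[tev$k == k & tev$l == l])
      })
      change <- sort(unique(c(sn$t_end_global[sn$t_end_global > loc2glob(st) &
                                                sn$t_end_global < loc2glob(en)] -
                                off + st,
                              tev$t_end)))

      out <- vector("list", length(starts))
      for (ai in seq_along(starts)) {
        a <- starts[ai]; b <- ends[ai]
        if (b < a) next  # defensive; validated logs do not produce this
        brk <- change[change > a & change < b]
        tt <- c(a, brk, b)
        m <- length(tt) - 1L
        if (m < 1L) { tt <- c(a, b); m <- 1L }
        rows <- matrix(0, m, 16)
        rows[, 1] <- ii
        rows[, 2] <- tt[-length(tt)]
        rows[, 3] <- tt[-1]
        for (k in 1:2) {
          gq <- loc2glob(rows[, 2])
          rows[, 3 + k] <- findInterval(gq, rew[[k]])
          rows[, 5 + k] <- findInterval(gq, om[[k]])
          rows[, 7 + k] <- findInterval(gq, oe[[k]])
          rows[, 9 + k] <- findInterval(gq, of[[k]])
        }
        for (j in 1:4) {
          idx <- findInterval(rows[, 2], tsets[[j]])
          rows[, 11 + j] <- ifelse(idx > 0, tsets[[j]][pmax(idx, 1)],
                                   NA_real_)
        }
        rows[m, 16] <- evc[ai]
        out[[ai]] <- rows
      }
      si <- si + 1L
      segs[[si]] <- do.call(rbind, out)
    }
  }
  seg <- do.call(rbind, segs[seq_len(si)])
  if (is.null(seg)) seg <- matrix(0, 0, 16)

  X <- cbind(age_pup = as.numeric(fit_ind$age_class == "pup"),
             age_juvenile = as.numeric(fit_ind$age_class == "juvenile"),
             age_subadult = as.numeric(fit_ind$age_class == "subadult"),
             sexM = as.numeric(fit_ind$sex == "M"),
             dominant = as.numeric(fit_ind$dominance == "dominant"))
  structure(list(
    seg = seg,
    individuals = fit_ind,
    X = X,
    dominance = fit_ind$dominance,
    age_group = as.character(transient_age_group(fit_ind$age_class)),
    variant = variant,
    n_events = sum(seg[, 16] > 0)), class = "smfm_likelihood_data")
}

#' Log-likelihood of the rate model over an event log
#'
#' Computes the exact log-likelihood of all bout-initiation events of
#' non-demonstrator individuals as a competing-risks inhomogeneous point
#' process: the sum over events of the log initiation rate at the chosen
#' option minus the integrated hazard over all four options across every
#' at-risk interval, with the integrals in closed form per
#' piecewise-constant-state segment.
#'
#' Invalid parameters return `-Inf` with attribute `valid = FALSE` (so
#' samplers can reject rather than abort).
#'
#' @param params an [smfm_params()].
#' @param log a validated [event_log()]; alternatively supply `data`.
#' @param variant an [smfm_variant()].
#' @param data a precompiled [prepare_likelihood_data()] result (must have
#'   been built with the same `variant`).
#' @return an object of class `smfm_loglik`: list with `loglik`,
#'   `n_events`, `n_segments`, `valid`.
#' @export
smfm_log_likelihood <- function(params, log = NULL,
                                variant = smfm_variant(), data = NULL) {
  if (is.null(data)) data <- prepare_likelihood_data(log, variant)
  if (!validate_smfm_params(params, stop_on_error = FALSE)) {
    out <- list(loglik = -Inf, n_events = data$n_events,
                n_segments = nrow(data$seg), valid = FALSE)
    class(out) <- "smfm_loglik"
    return(out)
  }
  fi <- data$individuals
  b <- setNames(numeric(ncol(data$X)), colnames(data$X))
  bn <- intersect(names(params$beta), names(b))
  b[bn] <- params$beta[bn]
  uu <- if (length(params$u)) {
    m <- match(fi$id, names(params$u))
    ifelse(is.na(m), 0, params$u[m])
  } else 0
  vv <- if (length(params$v)) {
    m <- match(fi$group_id, names(params$v))
    ifelse(is.na(m), 0, params$v[m])
  } else 0
  lp <- as.vector(data$X %*% b) + uu + vv
  lambda <- unname(params$lambda[data$dominance])
  ag <- data$age_group
  tr_on <- data$variant$transient
  gg <- if (tr_on) unname(params$g_general[ag]) else numeric(nrow(fi))
  gb <- if (tr_on) unname(params$g_box[ag]) else numeric(nrow(fi))
  gst <- if (tr_on) unname(params$g_sametype[ag]) else numeric(nrow(fi))
  gs <- if (tr_on) unname(params$g_specific[ag]) else numeric(nrow(fi))
  res <- smfm_loglik_cpp(data$seg, unname(params$r[1]), unname(params$r[2]),
                         lp, lambda, params$gamma,
                         unname(params$s[["manipulation"]]),
                         unname(params$s[["entry"]]),
                         unname(params$s[["feeding"]]),
                         gg, gb, gst, gs, params$rho,
                         data$variant$composition == "multiplicative")
  out <- list(loglik = res$loglik, n_events = res$n_events,
              n_segments = res$n_segments, valid = TRUE)
  class(out) <- "smfm_loglik"
  out
}

#' @export
print.smfm_loglik <- function(x, ...) {
  cat(sprintf("<smfm_loglik> %.4f (%d events, %d segments%s)\n",
              x$loglik, x$n_events, x$n_segments,
              if (x$valid) "" else ", INVALID PARAMS"))
  invisible(x)
}
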