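#' Compile an event log into per-individual experience timelines
#'
#' Experience is everything an individual has accrued *prior to* a time
#' point: counts of its own rewarded (`R`) and unrewarded (`F`)
#' manipulations per option-type, counts of observations of others'
#' manipulations split by class (manipulation seen / box entry seen /
#' feeding seen), a solved-ever flag per option-type, and, per
#' (option-type, box), the time of the most recent observation of another
#' individual's manipulation within the current session (the clock feeding
#' the transient social kernels).
#'
#' Counters step at bout / observation *end* times and carry over across
#' sessions; the observation clock resets at each session start.  All
#' queries are left-continuous: an event ending exactly at `t` is not yet
#' part of the experience at `t`.  Observation classes are nested: every
#' observation counts as a manipulation seen; those with `saw_entry` also
#' count as an entry seen; those with `saw_feeding` also as a feeding seen.
#'
#' @param log a validated [event_log()].
#' @return an object of class `smfm_experience`.
#' @seealso [experience_counts()], [last_observation_times()]
#' @export
build_experience_timeline <- function(log) {
  validate_event_log(log)
  ses <- log$sessions
  # global clock: sessions of a group are concatenated in index order
  ses <- ses[order(ses$group_id, ses$index), , drop = FALSE]
  dur <- ses$end_time - ses$start_time
  ses$offset <- stats::ave(dur, ses$group_id,
                           FUN = function(d) cumsum(c(0, d[-length(d)])))
  bt <- log$bouts
  bt <- bt[bt$option_type %in% OPTION_TYPES, , drop = FALSE]
  si <- match(bt$session_id, ses$session_id)
  own <- data.frame(
    individual_id = bt$individual_id,
    session_id = bt$session_id,
    k = match(bt$option_type, OPTION_TYPES),
    l = match(bt$box_side, BOX_SIDES),
    t_end = bt$t_end,
    t_end_global = ses$offset[si] + (bt$t_end - ses$start_time[si]),
    rewarded = bt$outcome == "solved",
    stringsAsFactors = FALSE)

  obs <- log$observations
  bi <- match(obs$target_bout_id, log$bouts$bout_id)
  keep <- log$bouts$option_type[bi] %in% OPTION_TYPES
  obs <- obs[keep, , drop = FALSE]; bi <- bi[keep]
  osi <- match(log$bouts$session_id[bi], ses$session_id)
  seen <- data.frame(
    individual_id = obs$observer_id,
    session_id = log$bouts$session_id[bi],
    k = match(log$bouts$option_type[bi], OPTION_TYPES),
    l = match(log$bouts$box_side[bi], BOX_SIDES),
    t_end = obs$t_end,
    t_end_global = ses$offset[osi] + (obs$t_end - ses$start_time[osi]),
    saw_entry = obs$saw_entry,
    saw_feeding = obs$saw_feeding,
    stringsAsFactors = FALSE)

  structure(list(individuals = log$individuals, sessions = ses,
                 own = own, seen = seen),
            class = "smfm_experience")
}

#' @export
print.smfm_experience <- function(x, ...) {
  cat("<smfm_experience>\n")
  cat(sprintf("  %d individuals, %d own-bout events, %d observation events\n",
              nrow(x$individuals), nrow(x$own), nrow(x$seen)))
  invisible(x)
}

# rows of the tau-relevant event stream for one individual in one session.
# condition selects the observation class that starts/refreshes a transient
# effect; "all_present" replaces observations by all bouts of *others* in
# sessions the individual attends (end times).
tau_events <- function(exp, log = NULL, individual_id, session_id,
                       condition = c("manipulation", "entry", "feeding",
                                     "all_present")) {
  condition <- match.arg(condition)
  if (condition == "all_present") {
    if (is.null(log))
      stop("tau condition 'all_present' needs the event log", call. = FALSE)
    bt <- log$bouts
    keep <- bt$session_id == session_id & bt$individual_id != individual_id &
      bt$option_type %in% OPTION_TYPES
    bt <- bt[keep, , drop = FALSE]
    return(data.frame(k = match(bt$option_type, OPTION_TYPES),
                      l = match(bt$box_side, BOX_SIDES), t_end = bt$t_end))
  }
  sn <- exp$seen
  keep <- sn$individual_id == individual_id & sn$session_id == session_id
  if (condition == "entry") keep <- keep & sn$saw_entry
  if (condition == "feeding") keep <- keep & sn$saw_feeding
  sn[keep, c("k", "l", "t_end")]
}

#' Query experience counters at a time point
#'
#' Returns the counts of rewarded / unrewarded own manipulations, the
#' nested observation-class counts, and the solved-ever flags per
#' option-type, for one individual just before local time `t` in a given
#' session (events from earlier sessions of the same group included).
#'
#' @param exp an `smfm_experience` from [build_experience_timeline()].
#' @param individual_id,session_id ids.
#' @param t session-local time in seconds.
#' @return list with `R`, `F` (length-2 counts, flap/tube), `O` (3 x 2
#'   matrix, rows manipulation/entry/feeding, columns flap/tube), and
#'   `solved_ever` (length-2 logical).
#' @export
experience_counts <- function(exp, individual_id, session_id, t) {
  g <- global_time(exp, session_id, t)
  ow <- exp$own
  ow <- ow[ow$individual_id == individual_id &
             same_group(exp, ow$session_id, session_id) &
             ow$t_end_global < g, , drop = FALSE]
  R <- Fl <- numeric(2); solved <- logical(2)
  for (k in 1:2) {
    R[k] <- sum(ow$k == k & ow$rewarded)
    Fl[k] <- sum(ow$k == k & !ow$rewarded)
    solved[k] <- R[k] > 0
  }
  sn <- exp$seen
  sn <- sn[sn$individual_id == individual_id &
             same_group(exp, sn$session_id, session_id) &
             sn$t_end_global < g, , drop = FALSE]
  O <- matrix(0, 3, 2, dimnames = list(OBS_CLASSES, OPTION_TYPES))
  for (k in 1:2) {
    O["manipulation", k] <- sum(sn$k == k)
    O["entry", k] <- sum(sn$k == k & sn$saw_entry)
    O["feeding", k] <- sum(sn$k == k & sn$saw_feeding)
  }
  list(R = setNames(R, OPTION_TYPES), F = setNames(Fl, OPTION_TYPES),
       O = O, solved_ever = setNames(solved, OPTION_TYPES))
}

#' Query the transient-effect clocks at a time point
#'
#' Gives, for each (option-type, box) pair, the session-local time of the
#' individual's most recent qualifying observation of another's
#' manipulation *within the queried session*, strictly before `t`.  `NA`
#' where no qualifying observation has yet occurred this session (the
#' transient effects are then absent).
#'
#' @inheritParams experience_counts
#' @param condition which observation class qualifies: any observed
#'   manipulation (default), only those where box entry was seen, only
#'   those where feeding was seen, or `"all_present"` (every bout by
#'   another individual qualifies, observed or not; requires `log`).
#' @param log the originating [event_log()]; only needed for
#'   `condition = "all_present"`.
#' @return 2 x 2 numeric matrix (rows flap/tube, columns left/right) of
#'   local times, `NA` where undefined.
#' @export
last_observation_times <- function(exp, individual_id, session_id, t,
                                   condition = "manipulation", log = NULL) {
  ev <- tau_events(exp, log, individual_id, session_id, condition)
  ev <- ev[ev$t_end < t, , drop = FALSE]
  tau <- matrix(NA_real_, 2, 2, dimnames = list(OPTION_TYPES, BOX_SIDES))
  for (k in 1:2) for (l in 1:2) {
    tt <- ev$t_end[ev$k == k & ev$l == l]
    if (length(tt)) tau[k, l] <- max(tt)
  }
  tau
}

global_time <- function(exp, session_id, t) {
  i <- match(session_id, exp$sessions$session_id)
  if (is.na(i)) stop("unknown session_id: ", session_id, call. = FALSE)
  exp$sessions$offset[i] + (t - exp$sessions$start_time[i])
}

same_group <- function(exp, session_ids, session_id) {
  g <- exp$sessions$group_id[match(session_id, exp$sessions$session_id)]
  exp$sessions$group_id[match(session_ids, exp$sessions$session_id)] == g
}
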