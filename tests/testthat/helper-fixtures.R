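# Hand-built two-individual log with known experience bookkeeping.
#
# Group G with individuals A (adult F subordinate) and B (juvenile M
# subordinate), two 100 s sessions.
#   S1: b1 A flap/left [10,20] solved; B observes [12,18] (entry+feeding)
#       b2 A tube/right [50,60] abandoned
#       b3 B flap/left [70,80] abandoned
#   S2: b4 B flap/left [30,40] solved; A observes [30,35] (entry only)
tiny_log <- function() {
  ind <- data.frame(
    id = c("A", "B"), group_id = "G",
    age_class = c("adult", "juvenile"), sex = c("F", "M"),
    dominance = "subordinate", is_demonstrator = FALSE,
    trained_option_type = NA_character_, stringsAsFactors = FALSE)
  ses <- data.frame(
    session_id = c("S1", "S2"), group_id = "G", index = 1:2,
    start_time = 0, end_time = 100, attendees = "A;B",
    stringsAsFactors = FALSE)
  bt <- data.frame(
    bout_id = c("b1", "b2", "b3", "b4"),
    session_id = c("S1", "S1", "S1", "S2"),
    individual_id = c("A", "A", "B", "B"),
    option_type = c("flap", "tube", "flap", "flap"),
    box_side = c("left", "right", "left", "left"),
    t_start = c(10, 50, 70, 30), t_end = c(20, 60, 80, 40),
    entered_box = c(TRUE, FALSE, FALSE, TRUE),
    obtained_food = c(TRUE, FALSE, FALSE, TRUE),
    outcome = c("solved", "abandoned", "abandoned", "solved"),
    stringsAsFactors = FALSE)
  obs <- data.frame(
    observer_id = c("B", "A"), target_bout_id = c("b1", "b4"),
    t_start = c(12, 30), t_end = c(18, 35),
    saw_entry = c(TRUE, TRUE), saw_feeding = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  event_log(ind, ses, bt, obs)
}

# small simulated log for oracle comparisons
small_sim_log <- function(seed = 1, n_ind = 6, n_sessions = 2,
                          session_length = 250, params = NULL,
                          p_obs = 0.5, variant = smfm_variant()) {
  roster <- default_roster(sizes = n_ind, demonstrators = "flap")
  des <- sim_design(individuals = roster, n_sessions = n_sessions,
                    session_length = session_length, p_obs = p_obs,
                    demo_bouts_per_session = 2, demo_bout_length = 10)
  if (is.null(params))
    params <- smfm_params(r = c(flap = 4e-4, tube = 3e-4),
                          lambda = c(subordinate = 0.1, dominant = 0.01),
                          s = c(manipulation = 0.001, entry = 0.01,
                                feeding = 0.005),
                          gamma = 2, g_general = 1, g_box = 2,
                          g_specific = 8, rho = log(2) / 20)
  simulate_experiment(params, outcome_model(), des, seed = seed,
                      variant = variant)$log
}

# Independent dense-grid likelihood: numerically integrates the rate
# function over each individual's at-risk time on a regular grid whose
# cells are split at every recorded event time (so no cell straddles a
# state change), and adds the log-rates at each initiation.
grid_loglik <- function(par, log, variant = smfm_variant(), dt = 0.01) {
  exp <- build_experience_timeline(log)
  ind <- log$individuals
  total <- 0
  for (id in ind$id[!ind$is_demonstrator]) {
    gid <- ind$group_id[ind$id == id]
    for (sj in which(log$sessions$group_id == gid)) {
      ses <- log$sessions[sj, ]
      if (!id %in% split_attendees(ses$attendees)[[1]]) next
      marks <- sort(unique(c(
        log$bouts$t_start[log$bouts$session_id == ses$session_id],
        log$bouts$t_end[log$bouts$session_id == ses$session_id],
        log$observations$t_end[
          log$observations$target_bout_id %in%
            log$bouts$bout_id[log$bouts$session_id == ses$session_id]])))
      edges <- sort(unique(c(
        seq(ses$start_time, ses$end_time, by = dt), ses$end_time,
        marks[marks > ses$start_time & marks < ses$end_time])))
      mid <- (edges[-1] + edges[-length(edges)]) / 2
      w <- diff(edges)
      own <- log$bouts[log$bouts$session_id == ses$session_id &
                         log$bouts$individual_id == id, ]
      at_risk <- rep(TRUE, length(mid))
      for (bi in seq_len(nrow(own)))
        at_risk[mid > own$t_start[bi] & mid < own$t_end[bi]] <- FALSE
      for (k in 1:2) for (l in 1:2) {
        rate <- interaction_rate(exp, id, ses$session_id, k, l, mid, par,
                                 variant, log)
        total <- total - sum(rate[at_risk] * w[at_risk])
      }
      evb <- own[own$option_type %in% c("flap", "tube"), ]
      for (bi in seq_len(nrow(evb))) {
        rate <- interaction_rate(exp, id, ses$session_id,
                                 evb$option_type[bi], evb$box_side[bi],
                                 evb$t_start[bi], par, variant, log)
        total <- total + log(rate)
      }
    }
  }
  total
}

# Brute-force experience replay: rescan the full log at a query time.
replay_counts <- function(log, id, session_id, t) {
  ses <- log$sessions
  ses <- ses[order(ses$group_id, ses$index), ]
  gid <- log$individuals$group_id[log$individuals$id == id]
  ses <- ses[ses$group_id == gid, ]
  qi <- match(session_id, ses$session_id)
  R <- Fl <- c(flap = 0, tube = 0)
  O <- matrix(0, 3, 2, dimnames = list(c("manipulation", "entry",
                                         "feeding"), c("flap", "tube")))
  before <- function(s, tt) {
    si <- match(s, ses$session_id)
    !is.na(si) && (si < qi || (si == qi && tt < t))
  }
  for (bi in seq_len(nrow(log$bouts))) {
    b <- log$bouts[bi, ]
    if (b$individual_id != id || !b$option_type %in% c("flap", "tube"))
      next
    if (before(b$session_id, b$t_end)) {
      if (b$outcome == "solved") R[b$option_type] <- R[b$option_type] + 1
      else Fl[b$option_type] <- Fl[b$option_type] + 1
    }
  }
  for (oi in seq_len(nrow(log$observations))) {
    o <- log$observations[oi, ]
    if (o$observer_id != id) next
    b <- log$bouts[log$bouts$bout_id == o$target_bout_id, ]
    if (!b$option_type %in% c("flap", "tube")) next
    if (before(b$session_id, o$t_end)) {
      O["manipulation", b$option_type] <-
        O["manipulation", b$option_type] + 1
      if (o$saw_entry) O["entry", b$option_type] <-
          O["entry", b$option_type] + 1
      if (o$saw_feeding) O["feeding", b$option_type] <-
          O["feeding", b$option_type] + 1
    }
  }
  list(R = R, F = Fl, O = O, solved_ever = R > 0)
}

replay_tau <- function(log, id, session_id, t) {
  tau <- matrix(NA_real_, 2, 2,
                dimnames = list(c("flap", "tube"), c("left", "right")))
  for (oi in seq_len(nrow(log$observations))) {
    o <- log$observations[oi, ]
    if (o$observer_id != id) next
    b <- log$bouts[log$bouts$bout_id == o$target_bout_id, ]
    if (b$session_id != session_id) next
    if (!b$option_type %in% c("flap", "tube")) next
    if (o$t_end < t && (is.na(tau[b$option_type, b$box_side]) ||
                          o$t_end > tau[b$option_type, b$box_side]))
      tau[b$option_type, b$box_side] <- o$t_end
  }
  tau
}

# exact shortest-window HPD by scanning every start index
brute_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1))
    if (x[i + m - 1] - x[i] < best[2] - best[1])
      best <- c(x[i], x[i + m - 1])
  best
}
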