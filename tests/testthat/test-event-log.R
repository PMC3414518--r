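test_that("write/read round-trips valid logs exactly", {
  log <- tiny_log()
  d <- withr::local_tempdir()
  write_event_log(log, d)
  expect_true(all(file.exists(file.path(
    d, c("individuals.csv", "sessions.csv", "bouts.csv",
         "observations.csv")))))
  expect_equal(read_event_log(d), log)

  sim <- small_sim_log(seed = 3)
  d2 <- withr::local_tempdir()
  write_event_log(sim, d2)
  expect_equal(read_event_log(d2), sim)
})

test_that("an empty roster-only log writes four tables with headers", {
  log <- event_log(tiny_log()$individuals, tiny_log()$sessions)
  d <- withr::local_tempdir()
  write_event_log(log, d)
  bt <- utils::read.csv(file.path(d, "bouts.csv"))
  expect_equal(nrow(bt), 0)
  expect_named(bt, c("bout_id", "session_id", "individual_id",
                     "option_type", "box_side", "t_start", "t_end",
                     "entered_box", "obtained_food", "outcome"))
  expect_equal(nrow(read_event_log(d)$observations), 0)
})

test_that("validation errors name the violated rule and row", {
  log <- tiny_log()
  bad <- log
  bad$observations$saw_entry[1] <- FALSE  # feeding without entry
  expect_error(validate_event_log(bad), "saw_feeding => saw_entry")

  bad <- log
  bad$bouts$t_start[2] <- 15  # overlaps A's bout b1 [10, 20]
  expect_error(validate_event_log(bad), "never overlap")

  bad <- log
  bad$observations$t_end[1] <- 25  # outside target bout [10, 20]
  expect_error(validate_event_log(bad), "inside target bout")

  bad <- log
  bad$bouts$obtained_food[3] <- TRUE  # abandoned but fed
  expect_error(validate_event_log(bad), "obtained_food|solved")

  bad <- log
  bad$individuals$trained_option_type[1] <- "flap"  # non-demonstrator
  expect_error(validate_event_log(bad), "trained_option_type")

  bad <- log
  bad$bouts$session_id[1] <- "nope"
  expect_error(validate_event_log(bad), "session_id")

  bad <- log
  bad$bouts$bout_id <- NULL
  expect_error(validate_event_log(bad), "missing columns")
})

test_that("a simulated multi-group experiment is valid by construction", {
  roster <- default_roster(sizes = c(8, 7, 6),
                           demonstrators = c("flap", "tube", "none"))
  sim <- simulate_experiment(
    study_params(), outcome_model(),
    sim_design(individuals = roster, n_sessions = 3,
               session_length = 400), seed = 11)
  expect_s3_class(sim$log, "smfm_event_log")
  expect_silent(validate_event_log(sim$log))
})

test_that("experience counters step at event end times", {
  exp <- build_experience_timeline(tiny_log())
  # b1 (A, flap, solved) ends at t = 20 in S1
  expect_equal(experience_counts(exp, "A", "S1", 20)$R[["flap"]], 0)
  expect_equal(experience_counts(exp, "A", "S1", 20.01)$R[["flap"]], 1)
  # B's observation of b1 ends at t = 18
  expect_equal(experience_counts(exp, "B", "S1", 18)$O["entry", "flap"], 0)
  expect_equal(experience_counts(exp, "B", "S1", 18.5)$O["entry", "flap"], 1)
  # counters carry across sessions: A's failure at tube persists into S2
  expect_equal(experience_counts(exp, "A", "S2", 0.5)$F[["tube"]], 1)
  # an individual with no bouts/observations before t has all-zero state
  z <- experience_counts(exp, "B", "S1", 5)
  expect_true(all(z$R == 0) && all(z$F == 0) && all(z$O == 0))
  expect_true(all(!z$solved_ever))
})

test_that("tau resets at session start and ignores own bouts", {
  exp <- build_experience_timeline(tiny_log())
  # B observed b1 (flap, left) until t = 18 in S1
  tau1 <- last_observation_times(exp, "B", "S1", 50)
  expect_equal(tau1["flap", "left"], 18)
  expect_true(all(is.na(tau1[c(2, 3, 4)])))
  # before any observation this session, tau is undefined even though
  # B observed in S1
  expect_true(all(is.na(last_observation_times(exp, "B", "S2", 100))))
  # A's own solved bout never sets A's tau
  expect_true(all(is.na(last_observation_times(exp, "A", "S1", 100))))
  # A's observation in S2 sets the (flap, left) clock at its end time
  expect_equal(last_observation_times(exp, "A", "S2", 50)["flap", "left"],
               35)
})

test_that("timelines match a brute-force replay of the log", {
  log <- small_sim_log(seed = 21, n_ind = 8, n_sessions = 3,
                       session_length = 200)
  exp <- build_experience_timeline(log)
  set.seed(99)
  ids <- sample(log$individuals$id, 4)
  for (id in ids) {
    for (sid in log$sessions$session_id) {
      for (t in runif(3, 0, 200)) {
        got <- experience_counts(exp, id, sid, t)
        want <- replay_counts(log, id, sid, t)
        expect_equal(unname(got$R), unname(want$R))
        expect_equal(unname(got$F), unname(want$F))
        expect_equal(unname(got$O), unname(want$O))
        expect_equal(unname(got$solved_ever), unname(want$solved_ever))
        expect_equal(unname(last_observation_times(exp, id, sid, t)),
                     unname(replay_tau(log, id, sid, t)))
      }
    }
  }
})

test_that("counters are monotone and conserve total bout counts", {
  log <- small_sim_log(seed = 5, n_ind = 6, n_sessions = 2)
  exp <- build_experience_timeline(log)
  last_sid <- log$sessions$session_id[nrow(log$sessions)]
  horizon <- log$sessions$end_time[nrow(log$sessions)] + 1
  for (id in log$individuals$id) {
    prev <- NULL
    for (t in seq(0, 200, by = 40)) {
      cur <- experience_counts(exp, id, last_sid, t)
      if (!is.null(prev)) {
        expect_true(all(cur$R >= prev$R))
        expect_true(all(cur$F >= prev$F))
        expect_true(all(cur$O >= prev$O))
      }
      prev <- cur
    }
    fin <- experience_counts(exp, id, last_sid, horizon)
    nb <- table(factor(
      log$bouts$option_type[log$bouts$individual_id == id],
      levels = c("flap", "tube")))
    expect_equal(unname(fin$R + fin$F), as.vector(nb))
  }
})
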