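# a one-individual log with a configurable bout list, for closed forms
one_ind_log <- function(bouts = NULL, T_len = 100) {
  ind <- data.frame(id = "X", group_id = "G", age_class = "adult",
                    sex = "F", dominance = "subordinate",
                    is_demonstrator = FALSE,
                    trained_option_type = NA_character_,
                    stringsAsFactors = FALSE)
  ses <- data.frame(session_id = "S1", group_id = "G", index = 1L,
                    start_time = 0, end_time = T_len, attendees = "X",
                    stringsAsFactors = FALSE)
  event_log(ind, ses, bouts, NULL)
}

test_that("with no events the log-likelihood is the survival of 4 risks", {
  log <- one_ind_log(T_len = 100)
  p <- smfm_params(r = c(flap = 0.003, tube = 0.003), gamma = 0)
  ll <- smfm_log_likelihood(p, log)
  expect_equal(ll$loglik, -4 * 0.003 * 100)
  expect_equal(ll$n_events, 0)
})

test_that("a single short bout contributes its log initiation rate", {
  r <- 0.002; T_len <- 100; eps <- 1e-6
  bt <- data.frame(bout_id = "b1", session_id = "S1", individual_id = "X",
                   option_type = "flap", box_side = "left",
                   t_start = 40, t_end = 40 + eps,
                   entered_box = FALSE, obtained_food = FALSE,
                   outcome = "abandoned", stringsAsFactors = FALSE)
  log <- one_ind_log(bt, T_len)
  p <- smfm_params(r = c(flap = r, tube = r), gamma = 0)
  ll <- smfm_log_likelihood(p, log)
  # exponential density: log r - 4 r T (up to the vanishing bout length)
  expect_equal(ll$loglik, log(r) - 4 * r * T_len, tolerance = 1e-6)
  expect_equal(ll$n_events, 1)
})

test_that("with learning and transients off the process is homogeneous", {
  log <- small_sim_log(seed = 31, n_ind = 6, n_sessions = 2,
                       session_length = 200)
  p0 <- smfm_params(r = c(flap = 3e-4, tube = 5e-4), gamma = 0)
  ll <- smfm_log_likelihood(p0, log)
  # closed form: sum of log r_k at events minus r_k times at-risk time
  ind <- log$individuals
  bt <- log$bouts
  non_demo <- !ind$is_demonstrator[match(bt$individual_id, ind$id)]
  ev <- bt[non_demo & bt$option_type %in% c("flap", "tube"), ]
  at_risk <- 0
  for (id in ind$id[!ind$is_demonstrator]) {
    for (sj in seq_len(nrow(log$sessions))) {
      ses <- log$sessions[sj, ]
      own <- bt[bt$individual_id == id & bt$session_id == ses$session_id, ]
      at_risk <- at_risk + (ses$end_time - ses$start_time) -
        sum(own$t_end - own$t_start)
    }
  }
  want <- sum(log(unname(p0$r[ev$option_type]))) -
    sum(p0$r) * 2 * at_risk
  expect_equal(ll$loglik, want, tolerance = 1e-10)
})

test_that("the analytic likelihood matches dense numerical integration", {
  for (seed in c(51, 52)) {
    log <- small_sim_log(seed = seed, n_ind = 5, n_sessions = 2,
                         session_length = 150)
    par <- smfm_params(r = c(flap = 4e-4, tube = 3e-4),
                       beta = c(sexM = 0.2, dominant = -0.2),
                       lambda = c(subordinate = 0.1, dominant = 0.02),
                       s = c(manipulation = 0.001, entry = 0.01,
                             feeding = 0.002),
                       gamma = 2, g_general = 1, g_box = 2,
                       g_sametype = 0.5, g_specific = 8, rho = 0.04)
    ll <- smfm_log_likelihood(par, log)
    expect_equal(ll$loglik, grid_loglik(par, log), tolerance = 1e-4)
  }
})

test_that("condition variants move the transient clocks consistently", {
  log <- small_sim_log(seed = 53, n_ind = 6, n_sessions = 2,
                       session_length = 150)
  par <- smfm_params(r = c(flap = 4e-4, tube = 3e-4),
                     lambda = c(subordinate = 0.1, dominant = 0.02),
                     gamma = 1, g_general = 1, g_box = 1, g_specific = 5,
                     rho = 0.05)
  for (cond in c("entry", "all_present")) {
    v <- smfm_variant(tau_condition = cond)
    ll <- smfm_log_likelihood(par, log, variant = v)
    expect_equal(ll$loglik, grid_loglik(par, log, v), tolerance = 1e-4,
                 info = cond)
  }
  # the no-transient variant equals setting all strengths to zero
  p0 <- smfm_params(r = par$r, lambda = par$lambda, gamma = par$gamma)
  expect_equal(
    smfm_log_likelihood(par, log, smfm_variant(transient = FALSE))$loglik,
    smfm_log_likelihood(p0, log)$loglik)
})

test_that("the multiplicative composition is supported end to end", {
  log <- small_sim_log(seed = 54, n_ind = 5, n_sessions = 1,
                       session_length = 150)
  par <- smfm_params(r = c(flap = 4e-4, tube = 3e-4),
                     lambda = c(subordinate = 0.1, dominant = 0.02),
                     gamma = 2, g_general = 1, g_box = 2, g_specific = 6,
                     rho = 0.05)
  v <- smfm_variant(composition = "multiplicative")
  expect_equal(smfm_log_likelihood(par, log, v)$loglik,
               grid_loglik(par, log, v), tolerance = 1e-4)
})

test_that("the rate is monotone in experience and strengths", {
  exp <- build_experience_timeline(tiny_log())
  base <- smfm_params(r = c(flap = 1e-3, tube = 1e-3),
                      lambda = c(subordinate = 0.05, dominant = 0.05),
                      s = c(manipulation = 0.001, entry = 0.004,
                            feeding = 0.002),
                      gamma = 2, g_general = 0.5, g_box = 1,
                      g_specific = 4, rho = 0.03)
  # B at S1 t = 90 has one reward-and-entry observation and one failure
  r0 <- interaction_rate(exp, "B", "S1", "flap", "left", 90, base)
  for (bump in list(c(g_specific = 8), c(g_box = 2), c(g_general = 1),
                    c(gamma = 3))) {
    args <- utils::modifyList(
      list(r = base$r, lambda = base$lambda, s = base$s,
           gamma = base$gamma, g_general = unname(base$g_general[1]),
           g_box = unname(base$g_box[1]),
           g_specific = unname(base$g_specific[1]), rho = base$rho),
      as.list(bump))
    p2 <- do.call(smfm_params, args)
    expect_gte(interaction_rate(exp, "B", "S1", "flap", "left", 90, p2),
               r0)
  }
  # more rewards cannot lower the rate: compare A before/after its reward
  rA0 <- interaction_rate(exp, "A", "S1", "flap", "left", 15, base)
  rA1 <- interaction_rate(exp, "A", "S1", "flap", "left", 25, base)
  expect_gte(rA1, rA0)
})

test_that("invalid parameters yield -Inf with a flag, not an error", {
  log <- one_ind_log(T_len = 50)
  p <- smfm_params()
  p$rho <- -1  # corrupt after construction
  ll <- smfm_log_likelihood(p, log)
  expect_identical(ll$loglik, -Inf)
  expect_false(ll$valid)
})
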