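test_that("association strength follows the count-based closed form", {
  expect_equal(association_strength(0, lambda = 0.3), 0)
  expect_equal(association_strength(2, lambda = 0.05), 1 - 0.95^2)
  # a single reward moves association by exactly the learning rate
  expect_equal(association_strength(1, lambda = 0.051), 0.051)
  # observation classes multiply in
  expect_equal(
    association_strength(1, O = c(entry = 3), lambda = 0.1,
                         s = c(entry = 0.02)),
    1 - 0.9 * 0.98^3)
  # monotone in every count, bounded by 1
  a <- vapply(0:50, function(R)
    association_strength(R, c(entry = R), 0.05, c(entry = 0.004)), 0.0)
  expect_true(all(diff(a) >= 0) && all(a < 1))
  expect_error(association_strength(1, lambda = 1), "\\[0, 1\\)")
  expect_error(association_strength(-1, lambda = 0.5), ">= 0")
})

test_that("transient kernels have the right structure at dt = 0", {
  st <- list(g_general = 1, g_box = 2, g_sametype = 0.5, g_specific = 8)
  tau <- matrix(NA_real_, 2, 2,
                dimnames = list(c("flap", "tube"), c("left", "right")))
  # no observation this session: all four addends are zero
  expect_equal(unname(transient_addend(10, tau, st, rho = 0.05)),
               matrix(0, 2, 2))
  # just observed a manipulation at (flap, left)
  tau["flap", "left"] <- 10
  ad <- transient_addend(10, tau, st, rho = 0.05)
  expect_equal(ad["flap", "left"],
               st$g_general + st$g_box + st$g_sametype + st$g_specific)
  expect_equal(ad["tube", "left"], st$g_general + st$g_box)
  expect_equal(ad["flap", "right"], st$g_general + st$g_sametype)
  expect_equal(ad["tube", "right"], st$g_general)
  # one half-life later every term has halved
  hl <- log(2) / 0.05
  expect_equal(unname(transient_addend(10 + hl, tau, st, rho = 0.05)),
               unname(ad) / 2)
  expect_error(transient_addend(5, tau, st, rho = 0.05), "earlier")
})

test_that("half-life maps the decay rate correctly", {
  expect_identical(half_life(log(2) / 20), 20)
  expect_equal(half_life(log(2)), 1)
  rho <- 0.1234
  expect_equal(half_life(2 * rho), half_life(rho) / 2)
  expect_equal(half_life(smfm_params(rho = log(2) / 7)), 7)
  expect_error(half_life(0), "> 0")
})

test_that("interaction rate reduces to the baseline without learning", {
  log <- tiny_log()
  exp <- build_experience_timeline(log)
  p0 <- smfm_params(r = c(flap = 0.002, tube = 0.001), gamma = 0)
  for (id in c("A", "B")) {
    expect_equal(interaction_rate(exp, id, "S1", "flap", "left", 95, p0),
                 0.002)
    expect_equal(interaction_rate(exp, id, "S2", "tube", "right", 95, p0),
                 0.001)
  }
  # gamma = 1, A = 0.5, no transients: rate = 1.5 r exp(LP)
  p1 <- smfm_params(r = c(flap = 0.002, tube = 0.001),
                    beta = c(sexM = 0.3), lambda = c(subordinate = 0.5,
                                                     dominant = 0.5))
  # A has one flap reward by t = 95 in S1, so A_assoc = 0.5
  expect_equal(interaction_rate(exp, "A", "S1", "flap", "left", 95, p1),
               1.5 * 0.002)
  # B is male: linear predictor exp(0.3); one flap reward by S2 t = 95
  expect_equal(interaction_rate(exp, "B", "S2", "flap", "left", 95, p1),
               1.5 * 0.002 * exp(0.3))
})

test_that("interaction rate matches an independent symbolic evaluation", {
  log <- small_sim_log(seed = 17, n_ind = 5, n_sessions = 2,
                       session_length = 200)
  exp <- build_experience_timeline(log)
  set.seed(42)
  par <- smfm_params(r = c(flap = runif(1, 1e-4, 1e-3),
                           tube = runif(1, 1e-4, 1e-3)),
                     beta = c(age_pup = 0.2, age_juvenile = -0.1,
                              age_subadult = 0.1, sexM = 0.25,
                              dominant = -0.3),
                     lambda = c(subordinate = 0.08, dominant = 0.01),
                     s = c(manipulation = 0.002, entry = 0.01,
                           feeding = 0.003),
                     gamma = runif(1, 0.5, 4),
                     g_general = c(adult = 0.5, juv_subadult = 1, pup = 2),
                     g_box = c(adult = 1, juv_subadult = 2, pup = 3),
                     g_sametype = 0.7, g_specific = 6,
                     rho = runif(1, 0.01, 0.1))
  ids <- log$individuals$id[!log$individuals$is_demonstrator]
  for (id in sample(ids, 3)) {
    sid <- sample(log$sessions$session_id, 1)
    t <- runif(1, 0, 200)
    k <- sample(1:2, 1); l <- sample(1:2, 1)
    got <- interaction_rate(exp, id, sid, k, l, t, par)
    # independent recomputation from first principles
    row <- log$individuals[log$individuals$id == id, ]
    cnt <- replay_counts(log, id, sid, t)
    A <- 1 - (1 - par$lambda[[row$dominance]])^cnt$R[k] *
      (1 - par$s[["manipulation"]])^cnt$O["manipulation", k] *
      (1 - par$s[["entry"]])^cnt$O["entry", k] *
      (1 - par$s[["feeding"]])^cnt$O["feeding", k]
    tau <- replay_tau(log, id, sid, t)
    agegrp <- c(pup = "pup", juvenile = "juv_subadult",
                subadult = "juv_subadult", adult = "adult")[[row$age_class]]
    dec <- function(tt) if (all(is.na(tt))) 0 else
      exp(-par$rho * (t - max(tt, na.rm = TRUE)))
    Tr <- par$g_general[[agegrp]] * dec(tau) +
      par$g_box[[agegrp]] * dec(tau[, l]) +
      par$g_sametype[[agegrp]] * dec(tau[k, ]) +
      par$g_specific[[agegrp]] * dec(tau[k, l])
    x <- c(row$age_class == "pup", row$age_class == "juvenile",
           row$age_class == "subadult", row$sex == "M",
           row$dominance == "dominant")
    lp <- sum(par$beta[c("age_pup", "age_juvenile", "age_subadult",
                         "sexM", "dominant")] * x)
    want <- unname(par$r[k]) * exp(lp) * (1 + par$gamma * A + Tr)
    expect_equal(got, unname(want), tolerance = 1e-12)
  }
})

test_that("segment integrals agree with adaptive quadrature", {
  log <- small_sim_log(seed = 23, n_ind = 5, n_sessions = 1,
                       session_length = 150)
  exp <- build_experience_timeline(log)
  par <- smfm_params(r = c(flap = 3e-4, tube = 2e-4),
                     lambda = c(subordinate = 0.1, dominant = 0.02),
                     s = c(manipulation = 0.001, entry = 0.008,
                           feeding = 0.002),
                     gamma = 2, g_general = 1, g_box = 2, g_specific = 8,
                     rho = 0.04)
  sid <- log$sessions$session_id[1]
  checked <- 0
  for (id in log$individuals$id[!log$individuals$is_demonstrator]) {
    # state-change times for this individual in the session
    own <- log$bouts[log$bouts$individual_id == id &
                       log$bouts$session_id == sid, ]
    oo <- log$observations[log$observations$observer_id == id, ]
    oo <- oo[log$bouts$session_id[match(oo$target_bout_id,
                                        log$bouts$bout_id)] == sid, ]
    marks <- sort(unique(c(0, own$t_start, own$t_end, oo$t_end, 150)))
    for (j in seq_len(length(marks) - 1)) {
      t0 <- marks[j]; t1 <- marks[j + 1]
      if (t1 - t0 < 1) next
      got <- segment_integrated_hazard(exp, id, sid, "flap", "left",
                                       t0, t1, par)
      want <- stats::integrate(function(tt)
        interaction_rate(exp, id, sid, "flap", "left", tt, par),
        t0, t1, rel.tol = 1e-10, abs.tol = 1e-12)$value
      expect_equal(got, want, tolerance = 1e-8)
      checked <- checked + 1
      if (checked >= 8) break
    }
    if (checked >= 8) break
  }
  expect_gte(checked, 3)

  # constant-rate segment: integral is r * L exactly
  exp0 <- build_experience_timeline(tiny_log())
  p0 <- smfm_params(r = c(flap = 0.01, tube = 0.01), gamma = 0)
  expect_equal(segment_integrated_hazard(exp0, "A", "S1", "flap", "left",
                                         20, 50, p0), 0.01 * 30)
  # a segment spanning a state change is refused
  expect_error(segment_integrated_hazard(exp0, "B", "S1", "flap", "left",
                                         10, 30, p0), "state change")
})

test_that("single transient term integrates to g/rho over a long window", {
  # B's observation clock at (flap, left) is 18 in S1 of the tiny log
  exp <- build_experience_timeline(tiny_log())
  par <- smfm_params(r = c(flap = 1, tube = 1), gamma = 0,
                     g_specific = 3, g_box = 0, g_general = 0, rho = 0.5)
  got <- segment_integrated_hazard(exp, "B", "S1", "flap", "left",
                                   18, 70, par)
  # baseline part 52 s plus nearly the full kernel mass g / rho
  expect_equal(got, 52 + 3 / 0.5 * (1 - exp(-0.5 * 52)), tolerance = 1e-12)
})

test_that("specificity reflects the kernel hierarchy", {
  # no option-specific or box kernels: choice between types is symmetric
  p <- smfm_params(g_general = 2, g_box = 0, g_specific = 0)
  expect_equal(specificity(p), 0.5)
  # box-level enhancement alone does not bias the option-type either
  p <- smfm_params(g_general = 1, g_box = 5, g_specific = 0)
  expect_equal(specificity(p), 0.5)
  # overwhelming specific enhancement pins the observed option
  p <- smfm_params(g_specific = 1e8, g_general = 1, g_box = 1)
  expect_gt(specificity(p), 0.999)
  # equal unit kernels, equal baselines: direct enumeration gives 6/11
  p <- smfm_params(g_general = 1, g_box = 1, g_specific = 1)
  expect_equal(specificity(p), 6 / 11)
})

test_that("specificity matches competing-risks first-choice frequencies", {
  p <- smfm_params(r = c(flap = 2e-4, tube = 2e-4), g_general = 1,
                   g_box = 1, g_specific = 1)
  # immediately after an observation at (flap, left) the four rates are
  # proportional to 1 + T_kl; simulate the first choice among competing
  # exponentials at those rates
  Tkl <- c(fl = 3, tl = 2, fr = 1, tr = 1)
  rates <- 2e-4 * (1 + Tkl)
  set.seed(7)
  n <- 20000
  draws <- matrix(rexp(4 * n, rate = rates), nrow = 4)
  first <- apply(draws, 2, which.min)
  mc <- mean(first %in% c(1, 3))  # flap on either box
  expect_equal(specificity(p), mc, tolerance = 0.01)
})
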