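mk_records <- function(duration, event, ...) {
  data.frame(duration = duration, event = event, ...,
             stringsAsFactors = FALSE)
}

test_that("the partial likelihood matches hand-enumerated risk sets", {
  # single event with two at risk, coefficient 0: log(1/2)
  r2 <- mk_records(c(1, 2), c(TRUE, FALSE), x = c(1, 0))
  expect_equal(cox_partial_loglik(r2, c(x = 0)), log(1 / 2))

  # four records, no ties: manual product over risk sets
  r4 <- mk_records(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, TRUE),
                   x = c(1, 0, 1, 0))
  b <- 0.7
  manual <- (b - log(exp(b) + 1 + exp(b) + 1)) +
    (0 - log(1 + exp(b) + 1)) +
    (0 - log(1))
  expect_equal(cox_partial_loglik(r4, c(x = b)), manual, tolerance = 1e-10)

  # at zero coefficients the loglik depends only on risk-set sizes
  expect_equal(cox_partial_loglik(r4, c(x = 0)), -log(4) - log(3) - log(1))

  # Efron's tie correction: two tied events, explicit formula
  rt <- mk_records(c(1, 1, 2), c(TRUE, TRUE, TRUE), x = c(1, 0, 1))
  w <- exp(c(b, 0, b))
  manual_efron <- (b + 0) -
    log(sum(w)) - log(sum(w) - mean(w[1:2])) -
    log(w[3]) + b
  expect_equal(cox_partial_loglik(rt, c(x = b)), manual_efron,
               tolerance = 1e-10)
  # Breslow uses the full denominator twice
  manual_breslow <- (b + 0) - 2 * log(sum(w)) + b - log(w[3])
  expect_equal(cox_partial_loglik(rt, c(x = b), ties = "breslow"),
               manual_breslow, tolerance = 1e-10)
  # without ties the two corrections coincide
  expect_equal(cox_partial_loglik(r4, c(x = b)),
               cox_partial_loglik(r4, c(x = b), ties = "breslow"))

  expect_error(cox_partial_loglik(mk_records(1:2, c(FALSE, FALSE),
                                             x = c(0, 1)), c(x = 0)),
               "no events")
})

test_that("Newton fitting matches the survival package", {
  skip_if_not_installed("survival")
  set.seed(11)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  z <- rnorm(n)
  tt <- rexp(n, rate = 0.1 * exp(0.5 * x - 0.3 * z))
  cens <- pmin(tt, 12)
  rec <- mk_records(cens, tt <= 12, x = x, z = z)
  fit <- fit_cox(rec, c("x", "z"))
  expect_true(fit$converged)
  sv <- survival::coxph(survival::Surv(duration, event) ~ x + z,
                        data = rec, ties = "efron")
  expect_equal(unname(fit$coef), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(fit$loglik, sv$loglik[2], tolerance = 1e-8)
  expect_equal(unname(sqrt(diag(fit$vcov))),
               unname(sqrt(diag(sv$var))), tolerance = 1e-5)
  expect_equal(fit$AIC, -2 * sv$loglik[2] + 4, tolerance = 1e-8)

  # null model: loglik at zero coefficients, AIC without penalty
  f0 <- fit_cox(rec, character(0))
  expect_equal(f0$loglik, cox_partial_loglik(rec, c(x = 0)))
  expect_equal(f0$AIC, -2 * f0$loglik)

  # duplicated covariate: rank-deficient design is refused
  rec$x2 <- rec$x
  expect_error(fit_cox(rec, c("x", "x2")), "rank")
})

test_that("a simulated log-hazard ratio of 0.5 is recovered", {
  set.seed(12)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, rate = 0.08 * exp(0.5 * x))
  cens <- pmin(tt, 20)
  rec <- mk_records(cens, tt <= 20, x = x)
  fit <- fit_cox(rec, "x")
  se <- sqrt(fit$vcov[1, 1])
  expect_lt(abs(fit$coef[["x"]] - 0.5), 3 * se)
})

test_that("Akaike weights follow the closed form and shift invariance", {
  w <- akaike_weights(c(100, 102))
  expect_equal(round(w, 3), c(0.731, 0.269))
  expect_equal(w[1], 1 / (1 + exp(-1)))
  expect_equal(sum(w), 1)
  expect_equal(akaike_weights(c(100, 102) + 57.3), w)
})

test_that("all-subsets averaging weighs evidence sensibly", {
  set.seed(13)
  n <- 500
  x <- rbinom(n, 1, 0.5)          # true effect, HR = 1.5
  n1 <- rnorm(n); n2 <- rnorm(n)  # null covariates
  tt <- rexp(n, rate = 0.1 * exp(log(1.5) * x))
  rec <- mk_records(pmin(tt, 15), tt <= 15, x = x, n1 = n1, n2 = n2)
  av <- all_subsets_average(rec, c("x", "n1", "n2"))
  expect_equal(attr(av, "n_models"), 8)
  expect_equal(sum(attr(av, "model_table")$weight), 1)
  expect_gt(av$weight[av$covariate == "x"],
            max(av$weight[av$covariate != "x"]))
  # the averaged multiplier brackets the generating hazard ratio
  i <- which(av$covariate == "x")
  expect_gt(av$uci_upper[i], 1.5 * 0.8)
  expect_lt(av$uci_lower[i], 1.5 * 1.2)

  # single-candidate set: with overwhelming evidence the averaged
  # coefficient approaches the conditional estimate
  av1 <- all_subsets_average(rec, "x")
  fx <- fit_cox(rec, "x")
  expect_equal(attr(av1, "n_models"), 2)
  if (av1$weight[1] > 0.95)
    expect_equal(av1$coef_avg[1], fx$coef[["x"]],
                 tolerance = 0.1)
  expect_error(all_subsets_average(rec, as.character(1:21)), "20")
})

test_that("bout tables freeze covariates at bout start", {
  log <- tiny_log()
  rho <- log(2) / 20
  solving <- build_bout_table(log, outcome = "solving", rho = rho)
  abandon <- build_bout_table(log, outcome = "abandonment", rho = rho)
  expect_equal(nrow(solving), 4)
  # complementary censoring between the two analyses
  expect_equal(sum(solving$event), 2)
  expect_equal(sum(abandon$event), 2)
  expect_equal(solving$event, !abandon$event)
  expect_equal(solving$duration, abandon$duration)

  s <- solving[order(solving$bout_id), ]
  # b1: A's first-ever bout, every experience covariate zero
  b1 <- s[s$bout_id == "b1", ]
  expect_true(all(b1[c("succ_same", "succ_other", "fail_same",
                       "fail_other", "solved_ever_same", "obs_feed_same",
                       "obs_feed_other", "recency")] == 0))
  expect_true(b1$event)
  # b2: A manipulating the tube after one flap success
  b2 <- s[s$bout_id == "b2", ]
  expect_equal(b2$succ_other, 1)
  expect_equal(b2$succ_same, 0)
  expect_equal(b2$solved_ever_same, 0)
  # b3: B watched A feed at the flap; A last left (flap, left) at t = 20
  b3 <- s[s$bout_id == "b3", ]
  expect_equal(b3$obs_feed_same, 1)
  expect_equal(b3$recency, exp(-rho * (70 - 20)))
  # b4: next session, recency clock reset, B carries its flap failure
  b4 <- s[s$bout_id == "b4", ]
  expect_equal(b4$recency, 0)
  expect_equal(b4$fail_same, 1)
  expect_true(b4$event)
})

test_that("demonstrator bouts are excluded from the bout table", {
  log <- small_sim_log(seed = 91)
  tab <- build_bout_table(log, outcome = "abandonment", rho = 0.03)
  demo <- log$individuals$id[log$individuals$is_demonstrator]
  expect_false(any(tab$individual_id %in% demo))
  nondemo_bouts <- log$bouts[
    !log$bouts$individual_id %in% demo &
      log$bouts$option_type %in% c("flap", "tube"), ]
  expect_equal(nrow(tab), nrow(nondemo_bouts))
})
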