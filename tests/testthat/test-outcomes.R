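test_that("deterministic arrivals are evenly spaced with drawn eligibility", {
  set.seed(1)
  p <- simulate_arrivals(rate = 100, horizon = 3)
  expect_equal(nrow(p), 300)
  expect_equal(p$arrival, (1:300) / 100)

  p2 <- simulate_arrivals(rate = 100, horizon = 10,
                          eligibility_probs = c(A1 = 0.9))
  n_inelig <- sum(!p2$elig_A1)
  expect_lt(abs(n_inelig - 100), 3 * sqrt(1000 * 0.9 * 0.1) + 1)
  expect_error(simulate_arrivals(0, 1), "rate")
  expect_error(simulate_arrivals(10, 0), "horizon")
})

test_that("poisson arrivals have the right count distribution", {
  set.seed(2)
  counts <- replicate(50, nrow(simulate_arrivals(20, 5, process = "poisson")))
  # mean count 100, sd 10; the mean of 50 draws has SE ~ 1.4
  expect_lt(abs(mean(counts) - 100), 3 * 10 / sqrt(50))
  expect_gt(stats::var(counts), 0)
})

test_that("binary event probabilities follow the logistic factorial model", {
  m <- outcome_model("binary", baseline = 0.2, effects = c(A1 = 0.5, B1 = 0.8))
  # no research interventions -> baseline
  expect_equal(event_probability(data.frame(A = "A0", B = "B0"), m), 0.2)
  # hand-computed: invlogit(logit(0.2) + log 0.5) = 1/9
  expect_equal(event_probability(data.frame(A = "A1", B = "B0"), m), 1 / 9,
               tolerance = 1e-12)
  # interaction multiplier 1 equals the product form
  m1 <- outcome_model("binary", 0.2, c(A1 = 0.5, B1 = 0.8),
                      interactions = c("A1:B1" = 1))
  both <- data.frame(A = "A1", B = "B1")
  expect_equal(event_probability(both, m1), event_probability(both, m))
  # a multiplier < 1 lowers the combined event odds further
  m2 <- outcome_model("binary", 0.2, c(A1 = 0.5, B1 = 0.8),
                      interactions = c("A1:B1" = 0.5))
  expect_lt(event_probability(both, m2), event_probability(both, m))

  set.seed(3)
  ev <- simulate_binary(data.frame(A = rep("A0", 20000), B = "B0"), m)
  expect_lt(abs(mean(ev) - 0.2), 3 * sqrt(0.2 * 0.8 / 20000))
  expect_error(simulate_binary(data.frame(A = "A9"), m, controls = c("A0")),
               "unknown intervention")
})

test_that("risk-ratio scale multiplies baseline risk directly", {
  m <- outcome_model("binary", 0.2, c(A1 = 0.5), effect_scale = "rr")
  expect_equal(event_probability(data.frame(A = "A1"), m), 0.1)
})

test_that("exponential survival times scale with the hazard ratio", {
  m <- outcome_model("tte", baseline = 0.5, effects = c(A1 = 0.5),
                     follow_up = 100)
  set.seed(4)
  o0 <- simulate_tte(data.frame(A = rep("A0", 20000)), m)
  expect_lt(abs(mean(o0$time) - 2), 3 * 2 / sqrt(20000))
  o1 <- simulate_tte(data.frame(A = rep("A1", 20000)), m)
  # hazard halved -> median doubles
  expect_lt(abs(stats::median(o1$time) / stats::median(o0$time) - 2), 0.2)
  # zero follow-up censors everything at 0
  m0 <- outcome_model("tte", 0.5, follow_up = 0)
  oz <- simulate_tte(data.frame(A = rep("A0", 10)), m0)
  expect_true(all(oz$status == 0) && all(oz$time == 0))
})

test_that("intermediate outcome concordance scales the treatment effect", {
  base <- list(baseline = 0.4)
  # rho = 1: intermediate equals the definitive formula at its own baseline
  m1 <- outcome_model("binary", 0.2, c(A1 = 0.5),
                      intermediate = c(base, rho = 1))
  set.seed(5)
  n <- 50000
  a <- data.frame(A = rep(c("A0", "A1"), each = n / 2))
  int1 <- simulate_intermediate(a, m1)
  p_trt <- mean(int1[a$A == "A1"]); p_ctl <- mean(int1[a$A == "A0"])
  lor <- log(p_trt / (1 - p_trt)) - log(p_ctl / (1 - p_ctl))
  expect_lt(abs(lor - log(0.5)), 0.1)

  # rho = 0: independent of arm
  m0 <- outcome_model("binary", 0.2, c(A1 = 0.5),
                      intermediate = c(base, rho = 0))
  int0 <- simulate_intermediate(a, m0)
  p <- stats::chisq.test(table(a$A, int0))$p.value
  expect_gt(p, 0.001)

  # rho = 0.5: intermediate log-OR is about half the definitive one
  mh <- outcome_model("binary", 0.2, c(A1 = 0.5),
                      intermediate = c(base, rho = 0.5))
  inth <- simulate_intermediate(a, mh)
  p_trt <- mean(inth[a$A == "A1"]); p_ctl <- mean(inth[a$A == "A0"])
  lorh <- log(p_trt / (1 - p_trt)) - log(p_ctl / (1 - p_ctl))
  expect_lt(abs(lorh - 0.5 * log(0.5)), 0.1)

  expect_error(outcome_model("binary", 0.2, c(A1 = 0.5),
                             intermediate = list(baseline = 0.4, rho = 2)),
               "rho")
})

test_that("null effects give exchangeable event rates across arms", {
  m <- outcome_model("binary", baseline = 0.3)
  set.seed(6)
  arms <- data.frame(A = sample(c("A0", "A1"), 20000, TRUE),
                     B = sample(c("B0", "B1"), 20000, TRUE))
  ev <- simulate_binary(arms, m)
  p <- stats::chisq.test(table(paste(arms$A, arms$B), ev))$p.value
  expect_gt(p, 0.001)
})

test_that("the simulated diluted control rate matches the planning arithmetic", {
  # B1 effective (RR 0.5), half of A0 patients receive it
  m <- outcome_model("binary", baseline = 0.2, effects = c(B1 = 0.5),
                     effect_scale = "rr")
  set.seed(7)
  n <- 40000
  arms <- data.frame(A = "A0", B = rep(c("B0", "B1"), each = n / 2))
  ev <- simulate_binary(arms, m)
  expected <- marginal_event_rate(0.2, data.frame(ratio = 0.5, fraction = 0.5))
  expect_lt(abs(mean(ev) - expected), 3 * sqrt(expected * (1 - expected) / n))
})

test_that("patient-level datasets are reproducible from the seed", {
  m <- outcome_model("binary", 0.3, c(A1 = 0.8))
  gen <- function(seed) {
    set.seed(seed)
    a <- simulate_arrivals(50, 2, eligibility_probs = c(A1 = 0.9))
    arms <- data.frame(A = sample(c("A0", "A1"), nrow(a), TRUE))
    cbind(a, arms, event = simulate_binary(arms, m, time = a$arrival))
  }
  expect_identical(gen(99), gen(99))
})
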