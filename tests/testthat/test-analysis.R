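# Hand-built two-stage dataset around a late-added arm A2:
# stage 1: A0 vs A1 only; stage 2: A0, A1, A2.
two_stage_data <- function(n1 = 60, n2 = 90, seed = 1) {
  set.seed(seed)
  d1 <- data.frame(id = 1:n1, stage = 1L,
                   arm_A = sample(rep(c("A0", "A1"), n1 / 2)),
                   mech_A = "randomised", stringsAsFactors = FALSE)
  d2 <- data.frame(id = n1 + 1:n2, stage = 2L,
                   arm_A = sample(rep(c("A0", "A1", "A2"), n2 / 3)),
                   mech_A = "randomised", stringsAsFactors = FALSE)
  d <- rbind(d1, d2)
  d$arrival <- d$id / 10
  d$event <- stats::rbinom(nrow(d), 1, 0.3)
  d
}

design_A3 <- function() {
  apply_adaptation(
    make_factorial_design(
      randomisations = list(
        list(id = "A", arms = list(list(id = "A0", role = "control"),
                                   list(id = "A1", role = "research")))),
      targets = 1000),
    adaptation("add_intervention", "A", 60, arm = list(id = "A2")))
}

test_that("concurrent-control selection excludes non-concurrent and non-randomised patients", {
  d <- two_stage_data()
  des <- design_A3()
  # A2 was only open in stage 2: stage-1 A0 patients are non-concurrent
  aset <- select_concurrent(d, des, "A2_vs_A0")
  expect_true(all(aset$data$stage == 2L))
  expect_setequal(levels(aset$data$arm), c("A0", "A2"))
  expect_true(all(aset$exclusions$reason == "non-concurrent stage"))
  expect_equal(sum(aset$exclusions$reason == "non-concurrent stage"), 30)
  # A1 vs A0 is concurrent in both stages
  aset1 <- select_concurrent(d, des, "A1_vs_A0")
  expect_setequal(unique(aset1$data$stage), c(1L, 2L))

  # preference/scheme-fixed allocations are excluded
  d2 <- d
  d2$mech_A[d2$id == 1] <- "not-eligible"
  aset2 <- select_concurrent(d2, des, "A1_vs_A0")
  expect_false(1 %in% aset2$data$id)
  expect_true("non-randomised allocation" %in% aset2$exclusions$reason)
  expect_error(select_concurrent(d, des, "Z1_vs_Z0"), "unknown comparison")
})

test_that("patients randomised to control after an arm stops are excluded", {
  des <- design_A3()
  des <- apply_adaptation(des, adaptation("stop_lack_of_benefit", "A1", 150))
  d <- two_stage_data()
  d3 <- data.frame(id = 151:200, stage = 3L,
                   arm_A = rep(c("A0", "A2"), 25), mech_A = "randomised",
                   arrival = 15 + 1:50 / 10,
                   event = stats::rbinom(50, 1, 0.3), stringsAsFactors = FALSE)
  dd <- rbind(d, d3)
  aset <- select_concurrent(dd, des, "A1_vs_A0")
  expect_false(any(aset$data$stage == 3L))
  expect_true(all(dd$id[dd$stage == 3 & dd$arm_A == "A0"] %in%
                    aset$exclusions$id))
})

test_that("eligibility for both arms is required for inclusion", {
  d <- two_stage_data()
  des <- design_A3()
  d$elig_A1 <- TRUE
  d$elig_A1[d$id %in% 1:5] <- FALSE  # delivered within trial but ineligible for A1
  aset <- select_concurrent(d, des, "A1_vs_A0")
  expect_false(any(1:5 %in% aset$data$id))
  expect_true("ineligible for one arm" %in% aset$exclusions$reason)
})

test_that("the stage-stratified MH estimate matches the closed-form oracle", {
  # perfect symmetry: OR 1, z 0
  d <- data.frame(id = 1:200, stage = 1L,
                  arm_A = rep(c("A0", "A1"), each = 100),
                  mech_A = "randomised",
                  event = rep(rep(c(1, 0), c(20, 80)), 2))
  des <- make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control"),
                                 list(id = "A1", role = "research")))),
    targets = 200)
  aset <- select_concurrent(d, des, "A1_vs_A0")
  r <- stage_stratified_test(aset, "binary")
  expect_equal(r$estimate, 0)
  expect_equal(r$z, 0)

  # two strata with known tables: research arm (a, b), control (c, d)
  # stage 1: a=10, b=90, c=20, d=80 ; stage 2: a=5, b=45, c=10, d=40
  mk <- function(stage, arm, ev, n) {
    data.frame(stage = stage, arm_A = arm, mech_A = "randomised",
               event = rep(c(1, 0), c(ev, n - ev)))
  }
  d2 <- rbind(mk(1, "A1", 10, 100), mk(1, "A0", 20, 100),
              mk(2, "A1", 5, 50), mk(2, "A0", 10, 50))
  d2$id <- seq_len(nrow(d2))
  # two-stage trajectory with A open throughout
  des2 <- apply_adaptation(des, adaptation(
    "add_randomisation", "B", 200,
    spec = list(id = "B", arms = list(list(id = "B0", role = "control"),
                                      list(id = "B1", role = "research")))))
  aset2 <- select_concurrent(d2, des2, "A1_vs_A0")
  r2 <- stage_stratified_test(aset2, "binary")
  # hand-computed MH sums: sum(a_k d_k / n_k) / sum(c_k b_k / n_k)
  num <- 10 * 80 / 200 + 5 * 40 / 100
  den <- 20 * 90 / 200 + 10 * 45 / 100
  expect_equal(r2$estimate, log(num / den), tolerance = 1e-12)
  # independent oracle: stats::mantelhaen.test on the same strata
  tab <- table(arm = factor(d2$arm_A, c("A0", "A1")), event = d2$event,
               stage = d2$stage)
  mh <- stats::mantelhaen.test(tab, correct = FALSE)
  expect_equal(exp(r2$estimate), unname(mh$estimate), tolerance = 1e-10)
  se_oracle <- (log(mh$conf.int[2]) - log(mh$conf.int[1])) /
    (2 * stats::qnorm(0.975))
  expect_equal(r2$se, se_oracle, tolerance = 1e-10)
  expect_gt(r2$z, 0)  # fewer events on research: benefit positive
})

test_that("uninformative strata are dropped without changing the estimate", {
  des <- make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control"),
                                 list(id = "A1", role = "research")))),
    targets = 1000)
  # open a second stage (new randomisation B) during which A stays open
  des <- apply_adaptation(des, adaptation(
    "add_randomisation", "B", 200,
    spec = list(id = "B", arms = list(list(id = "B0", role = "control"),
                                      list(id = "B1", role = "research")))))
  mk <- function(stage, arm, ev, n) {
    data.frame(stage = stage, arm_A = arm, mech_A = "randomised",
               event = rep(c(1, 0), c(ev, n - ev)))
  }
  with_zero <- rbind(mk(1, "A1", 10, 100), mk(1, "A0", 20, 100),
                     mk(2, "A1", 0, 40), mk(2, "A0", 0, 40))
  with_zero$id <- seq_len(nrow(with_zero))
  without <- with_zero[with_zero$stage == 1, ]
  r_with <- stage_stratified_test(select_concurrent(with_zero, des, "A1_vs_A0"),
                                  "binary")
  r_without <- stage_stratified_test(select_concurrent(without, des, "A1_vs_A0"),
                                     "binary")
  expect_equal(r_with$dropped_strata, 2L)
  expect_equal(r_with$estimate, r_without$estimate)
  expect_equal(r_with$se, r_without$se)

  # empty analysis set yields an explicit no-information result
  aset_e <- select_concurrent(without[0, ], des, "A1_vs_A0")
  r_e <- stage_stratified_test(aset_e, "binary")
  expect_false(r_e$informative)
  expect_true(is.na(r_e$z))
})

test_that("time-to-event comparisons use stage-stratified Cox/log-rank", {
  set.seed(31)
  n <- 600
  d <- data.frame(id = 1:n, stage = rep(1:2, each = n / 2),
                  arm_A = sample(rep(c("A0", "A1"), n / 2)),
                  mech_A = "randomised", stringsAsFactors = FALSE)
  m <- outcome_model("tte", baseline = 0.4, effects = c(A1 = 0.5),
                     follow_up = 3)
  o <- simulate_tte(d[, "arm_A", drop = FALSE], m)
  d$time <- o$time; d$status <- o$status
  des <- make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control"),
                                 list(id = "A1", role = "research")))),
    targets = n)
  des <- apply_adaptation(des, adaptation(
    "add_randomisation", "B", n / 2,
    spec = list(id = "B", arms = list(list(id = "B0", role = "control"),
                                      list(id = "B1", role = "research")))))
  aset <- select_concurrent(d, des, "A1_vs_A0")
  r <- stage_stratified_test(aset, "tte")
  expect_true(r$informative)
  expect_lt(abs(r$estimate - log(0.5)), 3 * r$se)
  expect_gt(r$z, 0)
  ref <- survival::coxph(survival::Surv(time, status) ~ arm_A +
                           survival::strata(stage), data = d)
  expect_equal(r$estimate, unname(stats::coef(ref)[1]), tolerance = 1e-8)
})

test_that("the combined dummy-variable model recovers simultaneous effects", {
  m <- outcome_model("binary", 0.3, effects = c(A1 = 0.5, B1 = 1))
  d <- make_2x2_dataset(20000, m, seed = 41)
  des <- design_2x2()
  cm <- combined_model(d, des, "binary")
  expect_setequal(cm$intervention, c("A1", "B1"))
  a1 <- cm[cm$intervention == "A1", ]
  b1 <- cm[cm$intervention == "B1", ]
  expect_lt(abs(a1$estimate - log(0.5)), 3 * a1$se)
  expect_lt(abs(b1$estimate), 3 * b1$se)
  expect_false(any(cm$flagged))

  # single-stage data: stage term dropped, equal to the unstratified fit
  fit <- stats::glm(event ~ I(arm_A == "A1") + I(arm_B == "B1"),
                    stats::binomial(), data = d)
  expect_equal(a1$estimate, unname(stats::coef(fit)[2]), tolerance = 1e-8)
})

test_that("interaction analysis reports subgroups and a homogeneity test", {
  m <- outcome_model("binary", 0.3, effects = c(A1 = 0.6, B1 = 0.8))
  d <- make_2x2_dataset(4000, m, seed = 43)
  des <- design_2x2()
  ia <- interaction_analysis(d, des, "B1_vs_B0", "A", "binary")
  expect_setequal(ia$subgroups$subgroup, c("A0", "A1"))
  expect_true(all(ia$subgroups$informative))
  expect_true(ia$interaction_p > 0 && ia$interaction_p <= 1)
  expect_error(interaction_analysis(d, des, "B1_vs_B0", "B", "binary"),
               "different randomisation")
  expect_error(interaction_analysis(d, des, "B1_vs_B0", "Z", "binary"),
               "no such randomisation")
})

test_that("late-added subgroups are strictly smaller in the interaction analysis", {
  model <- outcome_model("binary", 0.3)
  tr <- run_trial(design_adapted(target = 600, interim = 300), model,
                  seed = 5, stopping = FALSE, block_multiples = 1)
  ia <- interaction_analysis(tr$dataset, tr$trajectory, "B1_vs_B0", "A",
                             "binary")
  sub <- ia$subgroups
  expect_true(all(c("A0", "A1", "A2") %in% sub$subgroup))
  n_a2 <- sub$n[sub$subgroup == "A2"]
  expect_lt(n_a2, min(sub$n[sub$subgroup != "A2"]))
})

test_that("the homogeneity test holds its nominal size under no interaction", {
  m <- outcome_model("binary", 0.35, effects = c(A1 = 0.7, B1 = 1))
  des <- design_2x2()
  set.seed(47)
  reject <- logical(150)
  for (i in seq_along(reject)) {
    d <- make_2x2_dataset(400, m)
    ia <- interaction_analysis(d, des, "A1_vs_A0", "B", "binary")
    reject[i] <- ia$interaction_p < 0.05
  }
  # binomial band around 0.05 with 150 replicates
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 150))
})
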