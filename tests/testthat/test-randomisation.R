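randomise_n <- function(state, n, start = 1, ...) {
  for (i in seq_len(n)) {
    fmams:::engine_randomise(state, as.character(start + i - 1),
                             NA_real_, NULL, NULL, NULL)
  }
  state
}

test_that("a standard 2x2 patient receives one randomised arm per randomisation", {
  set.seed(1)
  st <- new_randomiser(design_2x2())
  rec <- randomise_patient(st, list(id = 1, time = 0.5))
  expect_equal(nrow(rec), 2)
  expect_true(all(rec$mechanism == "randomised"))
  expect_true(rec$assignment[rec$randomisation == "A"] %in% c("A0", "A1"))
  expect_true(rec$assignment[rec$randomisation == "B"] %in% c("B0", "B1"))
  # the B stratum records the realised A allocation
  expect_equal(rec$stratum[rec$randomisation == "B"],
               rec$assignment[rec$randomisation == "A"])
})

test_that("identical seed and patient stream reproduce the allocation log", {
  run <- function(seed) {
    set.seed(seed)
    st <- new_randomiser(design_2x2())
    randomise_n(st, 200)
    allocation_log(st)
  }
  expect_identical(run(42), run(42))
  expect_false(identical(run(42)$assignment, run(43)$assignment))
})

test_that("within-stratum imbalance never exceeds the open block's per-arm quota", {
  set.seed(7)
  st <- new_randomiser(design_2x2(), block_multiples = 2)  # b = 2k, quota 2
  for (i in 1:1000) {
    randomise_n(st, 1, start = i)
    if (i %% 100 == 0) {
      rep <- imbalance_report(st)
      expect_true(all(rep$imbalance$max_diff <= 2))
    }
  }
  # completed blocks are exactly balanced: with a single stratum per
  # randomisation A and blocks of 4, any multiple-of-4 prefix balances A
  log <- allocation_log(st)
  a <- log[log$randomisation == "A", ]
  blocks <- split(a$assignment, a$block)
  complete <- Filter(function(b) length(b) == 4, blocks)
  expect_gt(length(complete), 100)
  for (b in complete) expect_equal(as.integer(table(b)[c("A0", "A1")]), c(2L, 2L))
})

test_that("ineligible patients are delivered control and stratified as not-randomised", {
  set.seed(3)
  st <- new_randomiser(design_2x2())
  rec <- randomise_patient(st, list(id = "preg1",
                                    eligible = list(A = "A0")))
  a <- rec[rec$randomisation == "A", ]
  expect_equal(a$mechanism, "not-eligible")
  expect_equal(a$assignment, "A0")
  b <- rec[rec$randomisation == "B", ]
  expect_equal(b$mechanism, "randomised")
  expect_equal(b$stratum, "not-randomised")
})

test_that("reduced-set eligibility draws from blocks over the subset only", {
  set.seed(5)
  st <- new_randomiser(design_3way())
  for (i in 1:60) {
    rec <- randomise_patient(st, list(id = i, eligible = list(A = c("A0", "A2"))))
    expect_true(rec$assignment[rec$randomisation == "A"] %in% c("A0", "A2"))
  }
  log <- allocation_log(st)
  a <- log[log$randomisation == "A" & log$mechanism == "randomised", ]
  expect_setequal(unique(a$assignment), c("A0", "A2"))
  # full-eligibility patients use a different block family
  rec_full <- randomise_patient(st, list(id = 999))
  a_full <- rec_full[rec_full$randomisation == "A", ]
  expect_false(a_full$block %in% a$block)
})

test_that("non-consent yields a non-randomised record with the control delivered", {
  set.seed(9)
  st <- new_randomiser(design_2x2())
  rec <- randomise_patient(st, list(id = 1, consent = list(A = FALSE)))
  a <- rec[rec$randomisation == "A", ]
  expect_equal(a$mechanism, "not-consented")
  expect_equal(a$assignment, "A0")
  expect_equal(rec$mechanism[rec$randomisation == "B"], "randomised")
})

test_that("adding an arm closes old blocks and never reuses them", {
  set.seed(13)
  st <- new_randomiser(design_2x2())
  randomise_n(st, 101)  # leave an A block open mid-way
  blocks_before <- max(allocation_log(st)$block, na.rm = TRUE)
  adapt_randomiser(st, adaptation("add_intervention", "A", 101,
                                  arm = list(id = "A2")))
  randomise_n(st, 200, start = 102)
  log <- allocation_log(st)
  after <- log[log$sequence > 202 & log$randomisation == "A", ]
  expect_true(all(after$block > blocks_before))
  expect_true("A2" %in% after$assignment)
  expect_equal(st$stage_index, 2L)
  # later randomisation B now sees strata for A2 patients
  b_after <- log[log$randomisation == "B" & log$stratum == "A2", ]
  expect_gt(nrow(b_after), 0)
})

test_that("dropping from two-way vs three-way follows the block/stratum rules", {
  set.seed(17)
  # three-way drop: A blocks reopen over remaining arms, B strata continue
  st <- new_randomiser(design_3way())
  randomise_n(st, 90)
  adapt_randomiser(st, adaptation("stop_lack_of_benefit", "A1", 90))
  randomise_n(st, 90, start = 91)
  log <- allocation_log(st)
  late_a <- log[log$sequence > 180 & log$randomisation == "A", ]
  expect_false("A1" %in% late_a$assignment)
  expect_setequal(unique(late_a$assignment), c("A0", "A2"))
  # existing strata for B keep being used (A0 stratum appears before and after)
  b <- log[log$randomisation == "B" & log$stratum == "A0", ]
  expect_true(any(b$sequence <= 180) && any(b$sequence > 180))

  # two-way drop: randomisation discontinued, later strata 'not-randomised'
  st2 <- new_randomiser(design_3way())
  set.seed(19)
  randomise_n(st2, 30)
  adapt_randomiser(st2, adaptation("stop_lack_of_benefit", "B1", 30))
  rec <- randomise_patient(st2, list(id = "late"))
  b2 <- rec[rec$randomisation == "B", ]
  expect_equal(b2$mechanism, "scheme-fixed")
  expect_equal(b2$assignment, "all-B0")
  expect_error(adapt_randomiser(st2, adaptation("stop_lack_of_benefit", "B1", 40)),
               "discontinued")
})

test_that("weighted allocation fills blocks in proportion to arm weights", {
  d <- make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control", weight = 2),
                                 list(id = "A1", role = "research", weight = 1)))),
    targets = 100)
  set.seed(23)
  st <- new_randomiser(d, block_multiples = 1)  # blocks of 3: A0 A0 A1
  randomise_n(st, 300)
  log <- allocation_log(st)
  counts <- table(log$assignment)
  expect_equal(unname(counts["A0"]) / unname(counts["A1"]), 2)
})
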