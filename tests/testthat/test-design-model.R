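test_that("the initial scheme is the full cross of all randomisations", {
  d <- design_2x2()
  combos <- enumerate_arms(current_stage(d))
  expect_setequal(combos, c("A0+B0", "A1+B0", "A0+B1", "A1+B1"))
  expect_identical(combos, c("A0+B0", "A1+B0", "A0+B1", "A1+B1"))

  single <- make_factorial_design(
    randomisations = list(
      list(id = "A", arms = list(list(id = "A0", role = "control"),
                                 list(id = "A1", role = "research")))),
    targets = 100)
  expect_identical(enumerate_arms(current_stage(single)), c("A0", "A1"))

  triple <- apply_adaptation(design_2x2(), adaptation(
    "add_randomisation", "C", 0,
    spec = list(id = "C", arms = list(list(id = "C0", role = "control"),
                                      list(id = "C1", role = "research")))))
  expect_length(enumerate_arms(current_stage(triple)), 8)
  expect_true(all(c("A0+B0+C0", "A1+B1+C1") %in%
                    enumerate_arms(current_stage(triple))))
})

test_that("design construction validates its inputs", {
  expect_error(make_factorial_design(list(), targets = 10),
               "at least one randomisation")
  expect_error(make_factorial_design(
    list(list(id = "A", arms = list(list(id = "A1", role = "research"),
                                    list(id = "A2", role = "research")))),
    targets = 10), "exactly one control")
  expect_error(make_factorial_design(
    list(list(id = "A", arms = list(list(id = "X", role = "control"),
                                    list(id = "A1", role = "research"))),
         list(id = "B", arms = list(list(id = "B0", role = "control"),
                                    list(id = "A1", role = "research")))),
    targets = 10), "duplicate")
})

test_that("adding an arm to an existing randomisation yields the 3x2 scheme", {
  d <- design_adapted()
  combos <- enumerate_arms(current_stage(d))
  expect_setequal(combos, c("A0+B0", "A1+B0", "A2+B0",
                            "A0+B1", "A1+B1", "A2+B1"))
  expect_equal(current_stage(d)$index, 2L)
})

test_that("stopping the research arm of a two-way randomisation discontinues it", {
  d <- apply_adaptation(design_2x2(), adaptation("stop_lack_of_benefit", "B1", 1500))
  expect_identical(d$randomisations$B$status, "discontinued")
  expect_identical(d$randomisations$B$fixed_value, "all-B0")
  expect_identical(enumerate_arms(current_stage(d)), c("A0", "A1"))

  # with delivery of control disabled, the fixed label changes but the
  # scheme is identical
  d2 <- design_2x2(deliver_control_after_stop = FALSE)
  d2 <- apply_adaptation(d2, adaptation("stop_lack_of_benefit", "B1", 1500))
  expect_identical(d2$randomisations$B$fixed_value, "none")
  expect_identical(enumerate_arms(current_stage(d2)),
                   enumerate_arms(current_stage(d)))
})

test_that("stopping an arm of a three-way randomisation removes only that arm", {
  d <- apply_adaptation(design_adapted(),
                        adaptation("stop_lack_of_benefit", "A1", 2000))
  expect_identical(d$randomisations$A$status, "open")
  expect_setequal(d$randomisations$A$arms$id, c("A0", "A2"))
  combos <- enumerate_arms(current_stage(d))
  expect_false(any(grepl("A1", combos)))
})

test_that("illegal adaptations are rejected", {
  d <- design_2x2()
  expect_error(apply_adaptation(d, adaptation("stop_efficacy", "A0", 1)),
               "control")
  expect_error(apply_adaptation(d, adaptation("add_intervention", "A", 1,
                                              arm = list(id = "B1"))),
               "duplicate")
  dB <- apply_adaptation(d, adaptation("stop_lack_of_benefit", "B1", 1))
  expect_error(apply_adaptation(dB, adaptation("stop_lack_of_benefit", "B1", 2)),
               "discontinued")
  expect_error(apply_adaptation(dB, adaptation("add_intervention", "B", 2,
                                               arm = list(id = "B2"))),
               "discontinued")
})

test_that("stage trajectory invariants hold under random adaptation sequences", {
  set.seed(11)
  for (rep in 1:20) {
    d <- design_adapted()
    ops <- sample(c("stop", "addC"), 2)
    t <- 2000
    for (op in ops) {
      d <- tryCatch(switch(op,
        stop = apply_adaptation(d, adaptation(
          "stop_lack_of_benefit",
          sample(c("A1", "A2", "B1"), 1), t)),
        addC = apply_adaptation(d, adaptation(
          "add_randomisation", "C", t,
          spec = list(id = "C", arms = list(
            list(id = "C0", role = "control"),
            list(id = "C1", role = "research")))))),
        error = function(e) d)
      t <- t + 500
    }
    idx <- vapply(d$stages, `[[`, integer(1), "index")
    expect_identical(idx, seq_along(idx))
    for (k in seq_along(d$stages)[-1]) {
      expect_false(identical(d$stages[[k]]$scheme, d$stages[[k - 1]]$scheme))
    }
    # a stopped intervention never reappears in the enumeration
    stopped <- unlist(lapply(d$adaptations, function(a) {
      if (startsWith(a$kind, "stop")) a$target else NULL
    }))
    combos <- tryCatch(enumerate_arms(current_stage(d)), error = function(e) character(0))
    for (s in stopped) expect_false(any(grepl(s, combos, fixed = TRUE)))
  }
})

test_that("design config round-trips through yaml with identical stage schemes", {
  d <- design_adapted()
  d <- apply_adaptation(d, adaptation("stop_lack_of_benefit", "A1", 3000))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_design_config(d, path)
  d2 <- read_design_config(path)
  expect_equal(length(d2$stages), length(d$stages))
  for (k in seq_along(d$stages)) {
    expect_equal(d2$stages[[k]]$scheme, d$stages[[k]]$scheme)
  }
  expect_equal(d2$targets, d$targets)
  expect_error(read_design_config(yaml::as.yaml(list(targets = 10))),
               "invalid design config")
})
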