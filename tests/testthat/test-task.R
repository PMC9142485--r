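test_that("generated blocks satisfy the design composition for many seeds", {
  for (seed in 1:50) {
    cond <- if (seed %% 2) "identical" else "semantical"
    s <- generate_block(cond, seed)
    counts <- table(s$outcome)
    expect_equal(nrow(s), 240L)
    expect_equal(unname(counts["SAME"]), 180L)
    expect_equal(unname(counts["SIMI"]), 30L)
    expect_equal(unname(counts["DIFF"]), 30L)
    rl <- same_run_lengths(s)
    expect_true(all(rl >= 2 & rl <= 6))
    expect_equal(sum(rl), 180L)
  }
})

test_that("the correct square flips exactly after switch-signalling outcomes", {
  s_id <- generate_block("identical", 3)
  flips <- s_id$correct_square[-1] != s_id$correct_square[-240]
  should <- (s_id$outcome %in% c("SIMI", "DIFF"))[-240]
  expect_equal(flips, should)
  s_sem <- generate_block("semantical", 3)
  flips <- s_sem$correct_square[-1] != s_sem$correct_square[-240]
  should <- (s_sem$outcome == "DIFF")[-240]
  expect_equal(flips, should)
})

test_that("block generation is deterministic under a fixed seed", {
  expect_identical(generate_block("identical", 1),
                   generate_block("identical", 1))
  expect_false(identical(generate_block("identical", 1)$correct_square,
                         generate_block("identical", 2)$correct_square))
})

test_that("a lapse-free, perseveration-free agent is perfect from trial 2", {
  s <- generate_block("identical", 5)
  log <- simulate_agent(s, agent_policy(lapse_rate = 0,
                                        perseveration_rate = 0), seed = 9)
  expect_true(all(log$correct[-1]))
  sc <- score_behavior(s, log)
  expect_equal(sc$extinction_error_rate, 0)
  expect_equal(sc$association_error_rate, 0)
  expect_gte(sc$pct_correct, 100 * 239 / 240)
})

test_that("forced perseveration turns every post-reversal error into extinction", {
  s <- generate_block("identical", 5)
  log <- simulate_agent(s, agent_policy(lapse_rate = 0,
                                        perseveration_rate = 1), seed = 2)
  t2 <- 2:nrow(log)
  prev_shown <- log$shown_outcome[t2 - 1]
  prev_switch <- prev_shown %in% c("DIFF", "SIMI")  # identical condition
  n_err <- sum(!log$correct[t2])
  n_ext <- sum(prev_switch & log$choice[t2] == log$choice[t2 - 1] &
                 !log$correct[t2])
  expect_equal(n_ext, n_err)
  expect_gt(n_err, 0)
})

test_that("extinction rate tracks the perseveration probability", {
  s <- generate_block("identical", 2)
  rates <- sapply(c(0.05, 0.15, 0.4), function(p) {
    mean(sapply(1:25, function(i) {
      score_behavior(s, simulate_agent(
        s, agent_policy(lapse_rate = 0, perseveration_rate = p),
        seed = 1000 + i))$extinction_error_rate
    }))
  })
  # monotone in perseveration, and close to 100 p per opportunity
  expect_true(all(diff(rates) > 0))
  expect_lt(abs(rates[1] - 5), 2)
  expect_lt(abs(rates[2] - 15), 3.5)
})

test_that("hand-built logs reproduce the printed error definitions", {
  # one reversal (trial 4 SIMI, identical condition: switch signal);
  # the agent stays on trial 5 -> exactly one extinction error
  sched <- tiny_schedule(
    c("SAME", "SAME", "SAME", "SIMI", rep("SAME", 8)),
    c(rep("left", 4), rep("right", 8)))
  choices <- c(rep("left", 4), "left", rep("right", 7))
  sc <- score_behavior(sched, tiny_log(sched, choices))
  # two switch-signalled trials (after the SIMI, and after the error that
  # revealed DIFF); only the stay on trial 5 is an extinction error
  expect_equal(sc$extinction_error_rate, 100 * 1 / 2)
  expect_equal(sc$association_error_rate, 0)

  # correct SAME on trial 2, then an unprompted switch on trial 3
  sched2 <- tiny_schedule(rep("SAME", 12), rep("left", 12))
  choices2 <- c("left", "left", "right", rep("left", 9))
  sc2 <- score_behavior(sched2, tiny_log(sched2, choices2))
  expect_equal(sc2$extinction_error_rate, 0)
  # opportunities: every trial whose previous choice was a correct stay
  n_opp <- sum(choices2[-12] == "left")
  expect_equal(sc2$association_error_rate, 100 * 1 / n_opp)
})

test_that("scoring is invariant to relabeling left and right", {
  s <- generate_block("semantical", 8)
  log <- simulate_agent(s, agent_policy(), seed = 3)
  flip <- function(x) ifelse(x == "left", "right", "left")
  s2 <- s; s2$correct_square <- flip(s$correct_square)
  log2 <- log; log2$choice <- flip(log$choice)
  a <- score_behavior(s, log); b <- score_behavior(s2, log2)
  expect_equal(a$pct_correct, b$pct_correct)
  expect_equal(a$extinction_error_rate, b$extinction_error_rate)
  expect_equal(a$association_error_rate, b$association_error_rate)
})

test_that("behavior logs round-trip through TSV and mismatches error", {
  s <- generate_block("identical", 4)
  log <- simulate_agent(s, agent_policy(), seed = 6)
  path <- tempfile(fileext = ".tsv")
  write_behavior_tsv(log, path)
  log2 <- read_behavior_tsv(path)
  expect_equal(log$choice, log2$choice)
  expect_equal(log$rt_ms, log2$rt_ms, tolerance = 1e-9)
  expect_error(score_behavior(s, log[1:100, ]), "lengths differ")
})
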