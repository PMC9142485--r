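#' Generate one deterministic reversal-learning block
#'
#' Builds the outcome schedule of a single 240-trial block: 180 SAME, 30
#' SIMI and 30 DIFF outcomes, with every SIMI or DIFF preceded by a run of
#' 2-6 consecutive SAME trials (run lengths drawn uniformly). Outcome
#' categories describe the object revealed behind the *correct* square.
#' The correct square flips on the trial after any outcome that signals a
#' switch: DIFF in both conditions, and SIMI additionally in condition
#' "identical" (where only the exact target object counts as a hit). Square
#' sides are randomized uniformly per trial.
#'
#' @param condition `"identical"` or `"semantical"`
#' @param seed integer seed; the same seed reproduces the block exactly
#' @param block_id integer block label carried through to logs
#' @return object of class `trial_schedule`: data.frame with columns
#'   `trial`, `outcome` (factor SAME/SIMI/DIFF), `correct_square`
#'   (left/right), plus attributes `condition`, `block_id`,
#'   `object_triplet`.
#' @export
generate_block <- function(condition = c("identical", "semantical"),
                           seed, block_id = 1L) {
  condition <- match.arg(condition)
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  n_rare <- 60L   # 30 SIMI + 30 DIFF
  n_same <- 180L
  # run lengths of SAME before each rare outcome: uniform over all
  # compositions of 180 into 60 parts within [2,6] (the design constrains
  # the total, so lengths are sampled by exact DP-weighted enumeration)
  runs <- .sample_runs(n_rare, n_same, lo = 2L, hi = 6L)
  rare <- sample(rep(c("SIMI", "DIFF"), each = 30L))
  outcome <- character(0)
  for (i in seq_len(n_rare)) {
    outcome <- c(outcome, rep("SAME", runs[i]), rare[i])
  }
  stopifnot(length(outcome) == 240L)
  switch_after <- outcome == "DIFF" |
    (outcome == "SIMI" & condition == "identical")
  sq <- character(240L)
  sq[1] <- sample(c("left", "right"), 1)
  for (t in 2:240L) {
    sq[t] <- if (switch_after[t - 1]) setdiff(c("left", "right"), sq[t - 1]) else sq[t - 1]
  }
  triplets <- list(c("crown", "crown2", "lettuce"), c("drum", "drum2", "pumpkin"),
                   c("flower", "flower2", "tie"), c("hat", "hat2", "cake"),
                   c("mushroom", "mushroom2", "stool"), c("owl", "owl2", "barrel"))
  sched <- data.frame(
    trial = seq_len(240L),
    outcome = factor(outcome, levels = c("SAME", "SIMI", "DIFF")),
    correct_square = sq,
    stringsAsFactors = FALSE
  )
  attr(sched, "condition") <- condition
  attr(sched, "block_id") <- as.integer(block_id)
  attr(sched, "object_triplet") <- triplets[[sample.int(6L, 1)]]
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

# uniform sample of (r1..rk), lo <= ri <= hi, sum(ri) = total; sequential
# sampling weighted by the DP count of completions keeps it exactly uniform
.sample_runs <- function(k, total, lo = 2L, hi = 6L) {
  w <- hi - lo
  rem <- total - k * lo
  stopifnot(rem >= 0, rem <= k * w)
  # cnt[i+1, s+1] = number of ways i parts in [0, w] sum to s
  cnt <- matrix(0, k + 1L, rem + 1L)
  cnt[1L, 1L] <- 1
  for (i in seq_len(k)) {
    for (s in 0:rem) {
      lo_y <- max(0L, s - (i - 1L) * w)
      ys <- lo_y:min(w, s)
      cnt[i + 1L, s + 1L] <- sum(cnt[i, s - ys + 1L])
    }
  }
  y <- integer(k)
  s <- rem
  for (i in k:1L) {
    ys <- max(0L, s - (i - 1L) * w):min(w, s)
    p <- cnt[i, s - ys + 1L]
    y[k - i + 1L] <- ys[sample.int(length(ys), 1L, prob = p)]
    s <- s - y[k - i + 1L]
  }
  lo + sample(y)   # shuffle to remove any residual positional structure
}

#' Run lengths of SAME outcomes between successive rare outcomes
#' @param schedule a `trial_schedule`
#' @return integer vector of SAME-run lengths between non-SAME outcomes
#' @export
same_run_lengths <- function(schedule) {
  r <- rle(as.character(schedule$outcome) == "SAME")
  # runs of SAME bounded by rare outcomes on both sides, plus the leading
  # run (bounded by block start and the first rare outcome)
  r$lengths[r$values]
}

#' Agent policy for task simulation
#'
#' Stand-in for a human subject: follows the condition-specific stay/switch
#' rule, with a lapse probability of responding at random and a
#' perseveration probability of repeating the previous square when a
#' switch was signalled (producing extinction errors). Reaction times are
#' log-normal with a mean/sd (ms) that depends on the previous trial's
#' outcome category, mirroring the small RT modulation by outcome type.
#'
#' @param lapse_rate probability of a uniformly random choice
#' @param perseveration_rate probability of repeating the previous square
#'   after a switch signal
#' @param rt_ms named list per previous-outcome category (`SAME`, `SIMI`,
#'   `DIFF`, and `start` for trial 1) of `c(mean, sd)` in ms
#' @return object of class `agent_policy`
#' @export
agent_policy <- function(lapse_rate = 0.024, perseveration_rate = 0.072,
                         rt_ms = list(SAME = c(480, 150),
                                      SIMI = c(468, 150),
                                      DIFF = c(492, 160),
                                      start = c(550, 180))) {
  stopifnot(lapse_rate >= 0, lapse_rate <= 1,
            perseveration_rate >= 0, perseveration_rate <= 1)
  structure(list(lapse_rate = lapse_rate,
                 perseveration_rate = perseveration_rate,
                 rt_ms = rt_ms), class = "agent_policy")
}

#' Simulate an agent performing a block
#'
#' The agent chooses the square it believes correct: it stays after an
#' acceptable outcome and switches after a switch signal, except for
#' lapses and perseverations drawn from the policy. The outcome *shown* on
#' each trial is the scheduled category when the choice is correct; an
#' incorrect choice reveals an unrelated object (DIFF category), which the
#' agent treats as a switch signal.
#'
#' @param schedule a [generate_block()] schedule
#' @param policy an [agent_policy()]
#' @param seed integer seed
#' @return `behavior_log`: data.frame with `trial`, `block`, `condition`,
#'   `outcome` (scheduled), `shown_outcome`, `choice`, `correct`, `rt_ms`.
#' @export
simulate_agent <- function(schedule, policy = agent_policy(), seed) {
  stopifnot(inherits(schedule, "trial_schedule"))
  set.seed(as.integer(seed))
  condition <- attr(schedule, "condition")
  n <- nrow(schedule)
  choice <- character(n)
  shown <- character(n)
  rt <- numeric(n)
  correct <- logical(n)
  sides <- c("left", "right")
  believe <- sample(sides, 1)   # no information on trial 1
  prev_shown <- "start"
  for (t in seq_len(n)) {
    ch <- believe
    u <- stats::runif(1)
    if (u < policy$lapse_rate) ch <- sample(sides, 1)
    choice[t] <- ch
    correct[t] <- ch == schedule$correct_square[t]
    shown[t] <- if (correct[t]) as.character(schedule$outcome[t]) else "DIFF"
    pars <- policy$rt_ms[[prev_shown]]
    mu <- log(pars[1]^2 / sqrt(pars[1]^2 + pars[2]^2))
    sg <- sqrt(log(1 + pars[2]^2 / pars[1]^2))
    rt[t] <- stats::rlnorm(1, mu, sg)
    # belief update: switch signal = DIFF shown, or SIMI shown in
    # condition identical
    is_switch <- shown[t] == "DIFF" ||
      (shown[t] == "SIMI" && condition == "identical")
    target <- if (is_switch) setdiff(sides, ch) else ch
    if (is_switch && stats::runif(1) < policy$perseveration_rate) {
      target <- ch                       # perseveration: ignore the signal
    }
    believe <- target
    prev_shown <- shown[t]
  }
  log <- data.frame(trial = schedule$trial,
                    block = attr(schedule, "block_id"),
                    condition = condition,
                    outcome = as.character(schedule$outcome),
                    shown_outcome = shown,
                    choice = choice, correct = correct, rt_ms = rt,
                    stringsAsFactors = FALSE)
  class(log) <- c("behavior_log", "data.frame")
  log
}

#' Score a behavior log against its schedule
#'
#' Computes the behavioral summary in the conventions of the study:
#' percent correct; extinction errors (continuing to choose the incorrect
#' square after a reversal, i.e. an incorrect choice on a trial whose
#' previous shown outcome signalled a switch); association errors
#' (switching away from the previously chosen square although the previous
#' outcome was correct and signalled stay); and RT mean +/- sd per
#' previous-outcome category over correct trials.
#'
#' @param schedule the `trial_schedule` the log was produced from
#' @param log a `behavior_log` aligned to it
#' @return `behavior_summary`: list with `condition`, `pct_correct`,
#'   `extinction_error_rate` (percent of post-reversal trials),
#'   `association_error_rate` (percent of post-correct-stay trials), and
#'   `rt_by_prev_outcome` (data.frame: prev outcome, n, mean, sd over
#'   correct trials).
#' @export
score_behavior <- function(schedule, log) {
  if (nrow(schedule) != nrow(log)) {
    stop("schedule and log lengths differ (", nrow(schedule), " vs ",
         nrow(log), ")")
  }
  condition <- attr(schedule, "condition")
  n <- nrow(log)
  t2 <- 2:n
  prev_shown <- log$shown_outcome[t2 - 1]
  prev_choice <- log$choice[t2 - 1]
  prev_switch <- prev_shown == "DIFF" |
    (prev_shown == "SIMI" & condition == "identical")
  # extinction: switch was signalled but the subject chose the previously
  # (now incorrect) square again
  extinction <- prev_switch & log$choice[t2] == prev_choice &
    !log$correct[t2]
  # association: previous choice was correct and signalled stay, yet the
  # subject switched squares
  prev_stay_ok <- log$correct[t2 - 1] & !prev_switch
  association <- prev_stay_ok & log$choice[t2] != prev_choice
  # rates are per opportunity: extinction per post-reversal trial,
  # association per post-correct-stay trial (a per-trial denominator would
  # be incompatible with high overall accuracy alongside ~5-10% rates)
  rt_tab <- do.call(rbind, lapply(c("SAME", "SIMI", "DIFF"), function(oc) {
    sel <- t2[prev_shown == oc & log$correct[t2]]
    data.frame(prev_outcome = oc, n = length(sel),
               mean_ms = if (length(sel)) mean(log$rt_ms[sel]) else NA_real_,
               sd_ms = if (length(sel) > 1) stats::sd(log$rt_ms[sel]) else NA_real_)
  }))
  structure(list(
    condition = condition,
    pct_correct = 100 * mean(log$correct),
    extinction_error_rate = if (any(prev_switch))
      100 * sum(extinction) / sum(prev_switch) else 0,
    association_error_rate = if (any(prev_stay_ok))
      100 * sum(association) / sum(prev_stay_ok) else 0,
    rt_by_prev_outcome = rt_tab
  ), class = "behavior_summary")
}

#' Write or read a behavior log as TSV
#' @param log a `behavior_log`
#' @param path file path
#' @export
write_behavior_tsv <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavior_tsv
#' @export
read_behavior_tsv <- function(path) {
  log <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  class(log) <- c("behavior_log", "data.frame")
  log
}
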