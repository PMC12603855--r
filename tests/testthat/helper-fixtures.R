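# Hand-built micro-trial and independent oracles used across test files.

# Two-patient fixture: A on study 4 weeks with 2 ED visits in week 2 and one
# 3-night hospitalization in week 3; B on study 4 weeks with no events.
tiny_trial <- function() {
  structure(list(
    patients = data.frame(
      patient_id = c("A", "B"), arm = "SCC",
      days_on_study = c(28L, 28L), weeks_on_study = c(4L, 4L),
      stringsAsFactors = FALSE
    ),
    events = data.frame(
      patient_id = c("A", "A"), week = c(2L, 3L),
      ed_visits = c(2L, 0L), hospitalizations = c(0L, 1L),
      los_days = c(0, 3), stringsAsFactors = FALSE
    ),
    reports = NULL, seed = 1L
  ), class = "sch_trial")
}

# trial with daily reports where every patient reports a flat burden score
constant_burden_trial <- function(levels, weeks = 26L) {
  n <- length(levels)
  days <- weeks * 7L
  reports <- do.call(rbind, lapply(seq_len(n), function(i) {
    sev <- matrix(as.integer(levels[i]), nrow = days, ncol = 11,
                  dimnames = list(NULL, paste0("s", sprintf("%02d", 1:11))))
    cbind(data.frame(patient_id = paste0("P", i), day = seq_len(days),
                     reported = TRUE, stringsAsFactors = FALSE),
          as.data.frame(sev))
  }))
  structure(list(
    patients = data.frame(patient_id = paste0("P", seq_len(n)), arm = "SCC",
                          days_on_study = days, weeks_on_study = weeks,
                          stringsAsFactors = FALSE),
    events = data.frame(patient_id = character(), week = integer(),
                        ed_visits = integer(), hospitalizations = integer(),
                        los_days = numeric(), stringsAsFactors = FALSE),
    reports = reports, seed = 1L
  ), class = "sch_trial")
}

# Independent frontier oracle: a strategy lies on the frontier iff some
# willingness-to-pay makes it the strict NMB maximizer, solved exactly as
# an interval intersection over pairwise ICER bounds (no sorting/iteration
# shared with find_frontier()).
oracle_frontier <- function(outcomes) {
  r <- 10 - outcomes$effect
  c_ <- outcomes$cost
  n <- length(r)
  dominated <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && ((c_[j] < c_[i] && r[j] >= r[i]) ||
                 (c_[j] <= c_[i] && r[j] > r[i]))
    }, logical(1)))
  }, logical(1))
  on_front <- vapply(seq_len(n), function(i) {
    lo <- 0; hi <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      if (r[i] > r[j]) lo <- max(lo, (c_[i] - c_[j]) / (r[i] - r[j]))
      else if (r[i] < r[j]) hi <- min(hi, (c_[j] - c_[i]) / (r[j] - r[i]))
      else if (c_[i] >= c_[j]) return(FALSE)
    }
    lo < hi
  }, logical(1))
  list(frontier = outcomes$arm[on_front & !dominated],
       absolutely_dominated = outcomes$arm[dominated])
}

random_outcomes <- function(n) {
  data.frame(arm = paste0("S", seq_len(n)),
             cost = runif(n, 0, 30000),
             effect = runif(n, 0, 10), stringsAsFactors = FALSE)
}
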