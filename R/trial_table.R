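#' Trial and spike tables
#'
#' `trial_table()` builds and validates the canonical per-trial table used by
#' every analysis stage; `spike_table()` does the same for spike times. A trial
#' table has one row per trial with the stimuli, delay duration, optogenetic
#' condition, lick times and (possibly absent) outcome; a spike table has one
#' row per (unit, trial) with spike times in seconds relative to sample-odor
#' onset (t = 0; pre-sample times are negative).
#'
#' Supported tasks: `DNMS` (delayed non-match to sample), `DPA` (delayed paired
#' association), `GNG` (Go/No-go), `NMS_WOD` (non-match to sample without
#' delay), `MSDPA` (six-sample DPA) and `DUAL` (DPA with an inner GNG
#' distractor task during the delay).
#'
#' @param df A data.frame with the columns listed in [trial_columns()].
#'   `lick_times_s` may be a list-column of numeric vectors.
#' @return A validated `trial_table` (a data.frame subclass).
#' @export
trial_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(trial_columns(), names(df))
  if (length(missing_cols) > 0)
    stopf("trial table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  df <- df[trial_columns()]
  if (!is.list(df$lick_times_s))
    df$lick_times_s <- lapply(df$lick_times_s, function(x) as.numeric(x))
  df$lick_times_s <- lapply(df$lick_times_s, function(x) {
    x <- as.numeric(x)
    x[!is.na(x)]
  })
  for (col in c("delay_s", "laser_onset_s", "laser_duration_s",
                "resp_win_start_s", "resp_win_end_s"))
    df[[col]] <- as.numeric(df[[col]])
  df$trial_id <- as.integer(df$trial_id)
  df$laser_on <- as.logical(df$laser_on)
  class(df) <- c("trial_table", "data.frame")
  validate_trial_table(df)
  df
}

#' @rdname trial_table
#' @export
trial_columns <- function() {
  c("trial_id", "task", "subject_id", "genotype", "sample_odor", "test_odor",
    "relation", "delay_s", "distractor", "laser_on", "laser_onset_s",
    "laser_duration_s", "perturb_epoch", "resp_win_start_s", "resp_win_end_s",
    "lick_times_s", "outcome")
}

wm_tasks <- c("DNMS", "DPA", "GNG", "NMS_WOD", "MSDPA", "DUAL")
wm_samples <- paste0("S", 1:6)
wm_tests <- c("T1", "T2")
wm_relations <- c("match", "nonmatch", "paired", "unpaired", "go", "nogo")
wm_distractors <- c("none", "go", "nogo")
wm_epochs <- c("none", "baseline", "delay")
wm_genotypes <- c("ChR2", "control")
wm_outcomes <- c("hit", "miss", "false_alarm", "correct_rejection")

# Relations on which a lick is rewarded (a lick is "correct").
rewarded_relations <- c("nonmatch", "paired", "go")

# Sample -> test pairing per task. DNMS/NMS_WOD reuse the sample odors as the
# test set (S1 <-> T1, S2 <-> T2 name the same odors); DPA pairs S1-T1 and
# S2-T2 arbitrarily; the six-sample task pairs S1..S3 with T1 and S4..S6 with
# T2; GNG uses S1 as the Go cue and S2 as the No-go cue.
paired_test <- function(task, sample_odor) {
  idx <- match(sample_odor, wm_samples)
  if (task == "MSDPA") ifelse(idx <= 3, "T1", "T2") else paste0("T", idx)
}

expected_relation <- function(task, sample_odor, test_odor) {
  if (task == "GNG") return(ifelse(sample_odor == "S1", "go", "nogo"))
  same <- paired_test(task, sample_odor) == test_odor
  if (task %in% c("DNMS", "NMS_WOD")) ifelse(same, "match", "nonmatch")
  else ifelse(same, "paired", "unpaired")
}

check_enum <- function(x, allowed, col, allow_na = FALSE) {
  bad <- which(!(x %in% allowed) & !(allow_na & is.na(x)))
  if (length(bad) > 0)
    stopf("invalid %s value '%s' in trial-table row %d (allowed: %s)",
          col, as.character(x[bad[1]]), bad[1], paste(allowed, collapse = ", "))
}

#' @rdname trial_table
#' @export
validate_trial_table <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  if (anyDuplicated(df$trial_id))
    stopf("duplicated trial_id: %s",
          df$trial_id[duplicated(df$trial_id)][1])
  if (any(df$trial_id < 1L)) stopf("trial_id must be >= 1")
  check_enum(df$task, wm_tasks, "task")
  check_enum(df$genotype, wm_genotypes, "genotype")
  check_enum(df$sample_odor, wm_samples, "sample_odor")
  check_enum(df$test_odor, wm_tests, "test_odor", allow_na = TRUE)
  check_enum(df$relation, wm_relations, "relation")
  check_enum(df$distractor, wm_distractors, "distractor", allow_na = TRUE)
  check_enum(df$perturb_epoch, wm_epochs, "perturb_epoch")
  check_enum(df$outcome, wm_outcomes, "outcome", allow_na = TRUE)
  non_ms <- which(df$task != "MSDPA" & !(df$sample_odor %in% c("S1", "S2")))
  if (length(non_ms) > 0)
    stopf("invalid sample_odor '%s' in trial-table row %d: task %s uses S1/S2 only",
          df$sample_odor[non_ms[1]], non_ms[1], df$task[non_ms[1]])
  if (any(!is.finite(df$delay_s)) || any(df$delay_s <= 0))
    stopf("delay_s must be finite and > 0 (row %d)",
          which(!is.finite(df$delay_s) | df$delay_s <= 0)[1])
  bad_win <- which(!(df$resp_win_start_s < df$resp_win_end_s))
  if (length(bad_win) > 0)
    stopf("response window start must precede end (row %d)", bad_win[1])
  # laser fields present iff laser_on
  need <- df$laser_on
  bad <- which(need & (is.na(df$laser_onset_s) | is.na(df$laser_duration_s)))
  if (length(bad) > 0)
    stopf("laser_on trial lacks laser_onset_s/laser_duration_s (row %d)", bad[1])
  bad <- which(!need & (!is.na(df$laser_onset_s) | !is.na(df$laser_duration_s)))
  if (length(bad) > 0)
    stopf("laser fields present on a laser-off trial (row %d)", bad[1])
  # relation consistency under the task pairing map
  for (i in seq_len(nrow(df))) {
    task <- df$task[i]
    if (task == "GNG") {
      exp_rel <- expected_relation(task, df$sample_odor[i], NA)
    } else {
      if (is.na(df$test_odor[i]))
        stopf("test_odor is required for task %s (row %d)", task, i)
      exp_rel <- expected_relation(task, df$sample_odor[i], df$test_odor[i])
    }
    if (df$relation[i] != exp_rel)
      stopf("relation '%s' inconsistent with (%s, %s) under task %s pairing (row %d)",
            df$relation[i], df$sample_odor[i],
            as.character(df$test_odor[i]), task, i)
  }
  invisible(df)
}

#' @rdname trial_table
#' @param spikes A data.frame with columns `unit_id`, `trial_id` and
#'   `spike_times_s` (list-column of sorted numeric vectors).
#' @param trials The companion `trial_table` used to cross-check `trial_id`s.
#' @export
spike_table <- function(spikes, trials = NULL) {
  spikes <- as.data.frame(spikes, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("unit_id", "trial_id", "spike_times_s"), names(spikes))
  if (length(missing_cols) > 0)
    stopf("spike table is missing required column(s): %s",
          paste(missing_cols, collapse = ", "))
  spikes <- spikes[c("unit_id", "trial_id", "spike_times_s")]
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$trial_id <- as.integer(spikes$trial_id)
  if (!is.list(spikes$spike_times_s))
    spikes$spike_times_s <- lapply(spikes$spike_times_s, as.numeric)
  spikes$spike_times_s <- lapply(spikes$spike_times_s, as.numeric)
  for (i in seq_len(nrow(spikes))) {
    st <- spikes$spike_times_s[[i]]
    if (length(st) > 1 && any(diff(st) <= 0))
      stopf("spike times not strictly sorted for unit %s, trial %d (row %d)",
            spikes$unit_id[i], spikes$trial_id[i], i)
  }
  if (anyDuplicated(spikes[c("unit_id", "trial_id")]))
    stopf("duplicated (unit_id, trial_id) row in spike table")
  if (!is.null(trials)) {
    unknown <- setdiff(unique(spikes$trial_id), trials$trial_id)
    if (length(unknown) > 0)
      stopf("spike table references unknown trial_id(s): %s",
            paste(utils::head(unknown, 5), collapse = ", "))
  }
  class(spikes) <- c("spike_table", "data.frame")
  spikes
}

#' @export
print.trial_table <- function(x, ...) {
  cat(sprintf("<trial_table> %d trials, task(s): %s, %d subject(s)\n",
              nrow(x), paste(unique(x$task), collapse = "/"),
              length(unique(x$subject_id))))
  NextMethod()
}

#' @export
print.spike_table <- function(x, ...) {
  cat(sprintf("<spike_table> %d units, %d (unit, trial) rows, %d spikes\n",
              length(unique(x$unit_id)), nrow(x),
              sum(lengths(x$spike_times_s))))
  invisible(x)
}

# ---- TSV dialect -----------------------------------------------------------
# UTF-8, header row, tab-separated; list fields comma-joined; missing values
# as empty fields. Numbers are serialized with as.character(), which is
# lossless for doubles read back with as.numeric() and stable under
# write -> read -> write round trips.

fmt_field <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), "", ifelse(x, "TRUE", "FALSE")))
  ifelse(is.na(x), "", as.character(x))
}

fmt_list_field <- function(lst) {
  vapply(lst, function(v) paste(as.character(v), collapse = ","), character(1))
}

parse_list_field <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) numeric(0) else as.numeric(strsplit(s, ",", fixed = TRUE)[[1]])
  })
}

#' Read and write session files
#'
#' `load_session()` reads a trials TSV (and optionally a spikes TSV), validates
#' both and cross-checks trial references. `write_session()` writes them back
#' in the canonical dialect; `write_session(load_session(...))` is lossless.
#'
#' @param trials_path Path to a trials TSV file.
#' @param spikes_path Optional path to a spikes TSV file.
#' @return A list with elements `trials` (a [trial_table()]) and `spikes`
#'   (a [spike_table()] or `NULL`).
#' @export
load_session <- function(trials_path, spikes_path = NULL) {
  trials <- read_trials(trials_path)
  spikes <- if (!is.null(spikes_path)) read_spikes(spikes_path, trials) else NULL
  list(trials = trials, spikes = spikes)
}

#' @rdname load_session
#' @export
read_trials <- function(trials_path) {
  if (!file.exists(trials_path)) stopf("file not found: %s", trials_path)
  raw <- utils::read.delim(trials_path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(trial_columns(), names(raw))
  if (length(missing_cols) > 0)
    stopf("%s: missing required column(s): %s", trials_path,
          paste(missing_cols, collapse = ", "))
  empty_to_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  df <- data.frame(
    trial_id = as.integer(raw$trial_id),
    task = raw$task,
    subject_id = raw$subject_id,
    genotype = raw$genotype,
    sample_odor = raw$sample_odor,
    test_odor = empty_to_na(raw$test_odor),
    relation = raw$relation,
    delay_s = as.numeric(raw$delay_s),
    distractor = empty_to_na(raw$distractor),
    laser_on = as.logical(raw$laser_on),
    laser_onset_s = as.numeric(empty_to_na(raw$laser_onset_s)),
    laser_duration_s = as.numeric(empty_to_na(raw$laser_duration_s)),
    perturb_epoch = raw$perturb_epoch,
    resp_win_start_s = as.numeric(raw$resp_win_start_s),
    resp_win_end_s = as.numeric(raw$resp_win_end_s),
    stringsAsFactors = FALSE
  )
  df$lick_times_s <- parse_list_field(raw$lick_times_s)
  df$outcome <- empty_to_na(raw$outcome)
  trial_table(df)
}

#' @rdname load_session
#' @param trials A `trial_table`.
#' @export
read_spikes <- function(spikes_path, trials = NULL) {
  if (!file.exists(spikes_path)) stopf("file not found: %s", spikes_path)
  raw <- utils::read.delim(spikes_path, colClasses = "character",
                           na.strings = NULL, check.names = FALSE,
                           fileEncoding = "UTF-8")
  missing_cols <- setdiff(c("unit_id", "trial_id", "spike_times_s"), names(raw))
  if (length(missing_cols) > 0)
    stopf("%s: missing required column(s): %s", spikes_path,
          paste(missing_cols, collapse = ", "))
  df <- data.frame(unit_id = raw$unit_id,
                   trial_id = as.integer(raw$trial_id),
                   stringsAsFactors = FALSE)
  df$spike_times_s <- parse_list_field(raw$spike_times_s)
  spike_table(df, trials)
}

#' @rdname load_session
#' @param session A list as returned by `load_session()`.
#' @param trials_path,spikes_path Output paths.
#' @export
write_session <- function(session, trials_path, spikes_path = NULL) {
  write_trials(session$trials, trials_path)
  if (!is.null(session$spikes) && !is.null(spikes_path))
    write_spikes(session$spikes, spikes_path)
  invisible(c(trials_path, spikes_path))
}

#' @rdname load_session
#' @export
write_trials <- function(trials, trials_path) {
  out <- data.frame(
    trial_id = fmt_field(trials$trial_id),
    task = fmt_field(trials$task),
    subject_id = fmt_field(trials$subject_id),
    genotype = fmt_field(trials$genotype),
    sample_odor = fmt_field(trials$sample_odor),
    test_odor = fmt_field(trials$test_odor),
    relation = fmt_field(trials$relation),
    delay_s = fmt_field(trials$delay_s),
    distractor = fmt_field(trials$distractor),
    laser_on = fmt_field(trials$laser_on),
    laser_onset_s = fmt_field(trials$laser_onset_s),
    laser_duration_s = fmt_field(trials$laser_duration_s),
    perturb_epoch = fmt_field(trials$perturb_epoch),
    resp_win_start_s = fmt_field(trials$resp_win_start_s),
    resp_win_end_s = fmt_field(trials$resp_win_end_s),
    lick_times_s = fmt_list_field(trials$lick_times_s),
    outcome = fmt_field(trials$outcome),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, trials_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(trials_path)
}

#' @rdname load_session
#' @export
write_spikes <- function(spikes, spikes_path) {
  out <- data.frame(
    unit_id = spikes$unit_id,
    trial_id = fmt_field(spikes$trial_id),
    spike_times_s = fmt_list_field(spikes$spike_times_s),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, spikes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(spikes_path)
}

# Per-trial recording span [-1, resp_win_end_s]: 1 s of pre-sample baseline
# through the end of the response window.
trial_span <- function(trials) {
  cbind(start = rep(-1, nrow(trials)), end = trials$resp_win_end_s)
}
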