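# Shared probe builders and a per-session cache for expensive fixtures.

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.cache[[name]])) .cache[[name]] <- force(expr)
  .cache[[name]]
}

# Pure tone: f Hz, dur seconds, sampled at fs.
tone <- function(f, dur, fs, amp = 1) {
  amp * sin(2 * pi * f * seq(1 / fs, dur, by = 1 / fs))
}

# A 19-channel recording where every channel holds the same series.
flat_recording <- function(x, fs, group = NULL, subject_id = "probe") {
  eeg_recording(matrix(rep(x, each = 19), nrow = 19), channels_1020(), fs,
                subject_id = subject_id, group = group)
}

# The default study cohort and its full feature matrix (expensive; built
# once per test session).
default_cohort <- function() cached("cohort", generate_cohort(cohort_config()))

default_fm <- function() cached("fm", cohort_features(default_cohort()))

# Group means of a feature-name prefix within a feature matrix.
prefix_group_means <- function(fm, prefix) {
  cols <- grep(prefix, colnames(fm), value = TRUE)
  vapply(eeg_groups(), function(g)
    mean(as.matrix(fm[fm$group == g, cols, drop = FALSE])), numeric(1))
}
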