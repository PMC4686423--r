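# Shared fixtures, built in code and cached per test run.

.fixture_env <- new.env()

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

make_trials <- function(n, stim_s = 30, gap_s = 90, t0 = 30) {
  onsets <- t0 + (seq_len(n) - 1) * (stim_s + gap_s)
  trial_set(onsets, onsets + stim_s)
}

# 20-trial LFP with a +2.5 dB delta injection (used by several modules)
lfp_injected <- function() fixture("lfp25", function() {
  tr <- make_trials(20)
  g <- generate_lfp(max(tr$offsets) + 40, tr, delta_effect_db = 2.5,
                    seed = 3)
  list(g = g, trials = tr)
})

# pure 2 Hz tone helper
tone <- function(freq, dur_s, fs, amp = 1) {
  amp * sin(2 * pi * freq * seq(0, dur_s - 1 / fs, by = 1 / fs))
}
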