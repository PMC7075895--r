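# Shared fixtures, built once per test run and cached for every file.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

fix_lexicon <- function() fixture("lexicon", function() build_lexicon(seed = 42))

fix_corpus <- function() fixture("corpus", function()
  build_corpus(fix_lexicon(), seed = 42))

fix_model <- function() fixture("model", function()
  build_semantic_model(fix_corpus(), k = 100))

fix_freq <- function() fixture("freq", function()
  corpus_frequency_table(fix_corpus()))

# A short phonated test wave (no pauses), used wherever any valid
# preprocessed recording is needed; built once.
fix_wave <- function() fixture("wave", function() {
  prof <- subject_profile(base_f0 = 120, base_jitter = 1, base_shimmer = 4,
                          base_pause_rate = 0, base_speech_rate = 4)
  v <- synth_voice(prof, duration_s = 65, sample_rate = 16000, seed = 7)
  list(wave = v$wave[(30 * 16000):(33 * 16000)], sample_rate = 16000)
})

# Construct an sc_transcript directly (bypassing the lexicon) so POS-rule
# oracles can be stated exactly.
make_transcript <- function(tokens, tags,
                            lemmas = tokens,
                            fillers = rep(FALSE, length(tokens))) {
  structure(list(tokens = tokens, tags = tags, lemmas = lemmas,
                 fillers = fillers), class = "sc_transcript")
}

# Feature table with a chosen per-feature difference vector between two
# conditions, for Wilcoxon oracles.
table_with_diffs <- function(diffs, feature = "A-x", n_extra_features = 0) {
  n <- length(diffs)
  base <- stats::rnorm(n)
  rows <- list()
  for (s in seq_len(n)) {
    for (cond in c("A", "B")) {
      val <- if (cond == "A") base[s] + diffs[s] else base[s]
      row <- data.frame(subject_id = sprintf("S%02d", s), session = 1,
                        condition = cond, task = "Monologue",
                        stringsAsFactors = FALSE)
      row[[feature]] <- val
      if (n_extra_features > 0)
        for (k in seq_len(n_extra_features))
          row[[sprintf("A-extra%02d", k)]] <- stats::rnorm(1)
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}
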