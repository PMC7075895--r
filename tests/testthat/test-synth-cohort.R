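# Synthetic cohort generator: determinism, preconditions, planted
# structure, and the feature-level simulation instrument.

test_that("cohort_config validates its invariants", {
  expect_s3_class(cohort_config(), "sc_cohort_config")
  expect_error(cohort_config(n_subjects = 1))
  expect_error(cohort_config(duration_s = 61), "duration_s")
  expect_error(cohort_config(conditions = c("PBO", "PBO")))
})

test_that("null_effect_map plants nothing and default map is labelled per condition", {
  nm <- null_effect_map()
  expect_named(nm, c("PBO", "MDMA0.75", "MDMA1.5", "OT"))
  for (e in nm) {
    expect_equal(e$f0_shift, 0)
    expect_equal(e$jitter_shift, 0)
    expect_equal(e$pause_rate_shift, 0)
    expect_equal(e$concept_weight, 0)
    expect_equal(e$hapax_factor, 1)
  }
  dm <- default_effect_map()
  expect_equal(dm$PBO$f0_shift, 0)         # reference condition untouched
  expect_gt(dm$MDMA1.5$f0_shift, dm$MDMA0.75$f0_shift)
})

test_that("synth_voice is deterministic and rejects bad parameters", {
  prof <- subject_profile(base_f0 = 120, base_pause_rate = 6)
  v1 <- synth_voice(prof, duration_s = 62, sample_rate = 16000, seed = 3)
  v2 <- synth_voice(prof, duration_s = 62, sample_rate = 16000, seed = 3)
  expect_identical(v1$wave, v2$wave)
  v3 <- synth_voice(prof, duration_s = 62, sample_rate = 16000, seed = 4)
  expect_false(identical(v1$wave, v3$wave))
  expect_error(synth_voice(prof, duration_s = 30, sample_rate = 16000),
               "duration_s")
  expect_error(synth_voice(prof, effects = list(f0_shift = -500),
                           duration_s = 62, sample_rate = 16000),
               "f0")
  expect_error(synth_voice(prof, duration_s = 62, sample_rate = 8000),
               "sample_rate")
})

test_that("zero pause rate gives continuous phonation with no pauses", {
  prof <- subject_profile(base_f0 = 120, base_pause_rate = 0)
  v <- synth_voice(prof, duration_s = 62, sample_rate = 16000, seed = 5)
  expect_equal(nrow(v$truth$pause_intervals), 0)
  expect_equal(nrow(v$truth$utterance_intervals), 1)
  # downstream: no pauses detected in a slice of the phonated signal
  seg <- segment_pauses(v$wave[(16000 * 10):(16000 * 15)], 16000)
  expect_equal(nrow(seg$pauses), 0)
})

test_that("synth_transcript is deterministic, validates weight, and obeys the mixture", {
  lex <- fix_lexicon()
  prof <- subject_profile(verbosity = 300)
  t1 <- synth_transcript(prof, concept_weight = 0.3, lexicon = lex, seed = 9)
  t2 <- synth_transcript(prof, concept_weight = 0.3, lexicon = lex, seed = 9)
  expect_identical(t1, t2)
  expect_error(synth_transcript(prof, concept_weight = 1.5, lexicon = lex),
               "concept_weight")
  # w = 1: content tokens come from the concept topic only
  tw <- synth_transcript(prof, concept_weight = 1, lexicon = lex, seed = 11)
  toks <- strsplit(gsub("[[:punct:]]", "", tolower(tw)), "\\s+")[[1]]
  topic <- lex$topic[match(toks, lex$word)]
  content <- topic[!is.na(topic) & topic != "function"]
  expect_true(all(content == "concept"))
  # w = 0: essentially none do
  t0 <- synth_transcript(prof, concept_weight = 0, lexicon = lex, seed = 11)
  toks0 <- strsplit(gsub("[[:punct:]]", "", tolower(t0)), "\\s+")[[1]]
  topic0 <- lex$topic[match(toks0, lex$word)]
  content0 <- topic0[!is.na(topic0) & topic0 != "function"]
  expect_lt(mean(content0 == "concept"), 0.1)
})

test_that("generate_cohort writes a complete, consistent output tree", {
  out <- file.path(tempdir(), "cohort-unit")
  cfg <- cohort_config(n_subjects = 2, conditions = c("PBO", "OT"),
                       tasks = c("Monologue", "Description"),
                       duration_s = 62, sample_rate = 16000, seed = 21,
                       effect_map = null_effect_map(c("PBO", "OT")))
  res <- generate_cohort(cfg, out)
  m <- res$manifest
  expect_equal(nrow(m), 2 * 2 * 2)              # subjects x conditions x tasks
  expect_true(all(file.exists(m$audio_path)))
  expect_true(all(file.exists(m$transcript_path)))
  # Description rows carry annotations; Monologue rows never do
  expect_true(all(is.na(m$annotation_path[m$task == "Monologue"])))
  desc_ann <- m$annotation_path[m$task == "Description"]
  expect_true(all(!is.na(desc_ann) & file.exists(desc_ann)))
  # ground truth: one entry per manifest row
  expect_equal(length(res$truth), nrow(m))
  expect_true(file.exists(res$manifest_path))
  expect_true(file.exists(res$truth_path))
  expect_true(file.exists(file.path(out, "lexicon.tsv")))
  unlink(out, recursive = TRUE)
})

test_that("simulate_feature_table has the documented shape and plants its effect", {
  tab <- simulate_feature_table(n_subjects = 6, effect_size = 0, seed = 2)
  expect_equal(nrow(tab), 12)
  fc <- feature_columns(tab)
  expect_length(fc, 126)
  expect_length(domain_columns(tab, "acoustic"), 88)
  expect_length(domain_columns(tab, "semantic"), 21)
  expect_length(domain_columns(tab, "psycholinguistic"), 17)
  expect_identical(tab, simulate_feature_table(n_subjects = 6,
                                               effect_size = 0, seed = 2))
  # planted effect shifts the named features in the named direction
  tb <- simulate_feature_table(n_subjects = 200, effect_size = 1, seed = 3)
  truth <- attr(tb, "truth")
  expect_length(truth$effect_features, 5)
  for (f in truth$effect_features) {
    d <- tb[[f]][tb$condition == "DRUG"] - tb[[f]][tb$condition == "PBO"]
    expect_gt(mean(d), 0.5)   # planted 1.0 contrast-sd shift, n = 200
  }
  null_feats <- setdiff(feature_columns(tb), truth$effect_features)[1:5]
  for (f in null_feats) {
    d <- tb[[f]][tb$condition == "DRUG"] - tb[[f]][tb$condition == "PBO"]
    expect_lt(abs(mean(d)), 0.3)
  }
})

test_that("lexicon and corpus builders are deterministic and well formed", {
  lex <- fix_lexicon()
  expect_s3_class(lex, "sc_lexicon")
  expect_false(any(duplicated(lex$word)))
  expect_true(all(default_concepts() %in% lex$word))
  expect_identical(build_lexicon(seed = 42), lex)
  corp <- fix_corpus()
  expect_length(corp, 500)
  expect_identical(build_corpus(lex, seed = 42), corp)
  # round-trip through TSV
  p <- tempfile(fileext = ".tsv")
  write_lexicon(lex, p)
  lex2 <- read_lexicon(p)
  expect_equal(lex2$word, lex$word)
  expect_equal(lex2$pos, lex$pos)
  unlink(p)
})
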