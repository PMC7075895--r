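# Synthetic crossover cohort generation.
#
# One call produces everything the analysis pipeline consumes: a manifest,
# per-session WAV recordings and transcripts, interviewer-segment
# annotations for the Description task, a background corpus and lexicon for
# the semantic model, and a ground-truth record of every realized generator
# parameter for recovery testing.

#' Cohort configuration
#'
#' @param n_subjects number of participants (>= 2).
#' @param conditions ordered condition labels; every condition occurs once
#'   per subject per task.
#' @param tasks task labels. `Description` rows receive synthetic
#'   interviewer-segment annotations; `Monologue` rows none.
#' @param duration_s recording length per session, seconds (> 61).
#' @param sample_rate audio sampling rate, Hz (>= 16000).
#' @param seed master seed; the whole cohort is a pure function of the
#'   configuration including this seed.
#' @param effect_map per-condition offsets on generator parameters; see
#'   [default_effect_map()]. An all-zero map yields a global-null cohort.
#' @return list of class `sc_cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8,
                          conditions = c("PBO", "MDMA0.75", "MDMA1.5", "OT"),
                          tasks = c("Monologue", "Description"),
                          duration_s = 300, sample_rate = 22050, seed = 1,
                          effect_map = default_effect_map(conditions)) {
  stopifnot(n_subjects >= 2, length(conditions) >= 2,
            !anyDuplicated(conditions), length(tasks) >= 1)
  if (duration_s <= 61)
    stop("duration_s must exceed 61 seconds (got ", duration_s, ")",
         call. = FALSE)
  structure(list(n_subjects = n_subjects, conditions = conditions,
                 tasks = tasks, duration_s = duration_s,
                 sample_rate = sample_rate, seed = seed,
                 effect_map = effect_map),
            class = "sc_cohort_config")
}

#' Placeholder condition effect map
#'
#' The source study reports no effect sizes for any speech parameter, so
#' these defaults are explicit placeholders: moderate, plausible offsets
#' chosen once for simulation realism, not estimates of real drug effects.
#' Use [null_effect_map()] for calibration studies.
#'
#' @param conditions condition labels; the first is treated as the
#'   reference (all-zero offsets).
#' @return named list: per condition, offsets `f0_shift` (Hz),
#'   `jitter_shift` (percentage points), `pause_rate_shift` (per minute),
#'   `concept_weight` (added mixture weight in \[0,1\]), `hapax_factor`
#'   (multiplicative richness factor).
#' @export
default_effect_map <- function(conditions = c("PBO", "MDMA0.75", "MDMA1.5",
                                              "OT")) {
  zero <- list(f0_shift = 0, jitter_shift = 0, pause_rate_shift = 0,
               concept_weight = 0, hapax_factor = 1)
  em <- stats::setNames(rep(list(zero), length(conditions)), conditions)
  tweak <- function(em, cond, ...) {
    if (cond %in% names(em)) em[[cond]] <- utils::modifyList(em[[cond]],
                                                             list(...))
    em
  }
  em <- tweak(em, "MDMA0.75", f0_shift = 6, jitter_shift = 0.4,
              pause_rate_shift = -1.5, concept_weight = 0.25,
              hapax_factor = 1.1)
  em <- tweak(em, "MDMA1.5", f0_shift = 10, jitter_shift = 0.8,
              pause_rate_shift = -2.5, concept_weight = 0.35,
              hapax_factor = 1.15)
  em <- tweak(em, "OT", f0_shift = 3, jitter_shift = 0.2,
              pause_rate_shift = -0.5, concept_weight = 0.15,
              hapax_factor = 1)
  em
}

#' @rdname default_effect_map
#' @export
null_effect_map <- function(conditions = c("PBO", "MDMA0.75", "MDMA1.5",
                                           "OT")) {
  zero <- list(f0_shift = 0, jitter_shift = 0, pause_rate_shift = 0,
               concept_weight = 0, hapax_factor = 1)
  stats::setNames(rep(list(zero), length(conditions)), conditions)
}

effect_for <- function(effect_map, condition) {
  e <- effect_map[[condition]] %||% list()
  utils::modifyList(list(f0_shift = 0, jitter_shift = 0,
                         pause_rate_shift = 0, concept_weight = 0,
                         hapax_factor = 1), e)
}

# Draw a subject profile around population defaults
draw_profile <- function(n_topics, seed) {
  with_local_seed(seed, {
    pref <- rexp(n_topics) + 0.1
    subject_profile(
      base_f0 = runif(1, 95, 220),
      base_jitter = runif(1, 0.5, 2),
      base_shimmer = runif(1, 2, 6),
      base_pause_rate = runif(1, 4, 12),
      base_speech_rate = runif(1, 3, 5),
      topic_preference = pref / sum(pref),
      verbosity = round(runif(1, 300, 600))
    )
  })
}

# Overlay a higher-pitched interviewer voice inside the longest pauses and
# return the annotated intervals.
overlay_interviewer <- function(wave, sample_rate, pauses, seed, n_seg = 2) {
  pauses <- pauses[order(pauses$end - pauses$start, decreasing = TRUE), ]
  pauses <- pauses[(pauses$end - pauses$start) > 1.2, , drop = FALSE]
  n_seg <- min(n_seg, nrow(pauses))
  if (n_seg == 0)   # no pause long enough: leave the wave untouched
    return(list(wave = wave,
                annotations = data.frame(start_s = numeric(0),
                                         end_s = numeric(0))))
  ann <- with_local_seed(seed, {
    out <- matrix(0, n_seg, 2)
    for (k in seq_len(n_seg)) {
      dur <- min(pauses$end[k] - pauses$start[k] - 0.4,
                 runif(1, 0.8, 2.5))
      s <- pauses$start[k] + 0.2
      u <- synth_utterance(dur, f0 = 190, jitter_pct = 1, shimmer_pct = 4,
                           speech_rate = 4, sr = sample_rate)
      i0 <- floor(s * sample_rate) + 1
      i1 <- min(i0 + length(u$wave) - 1, length(wave))
      seg <- u$wave[seq_len(i1 - i0 + 1)]
      wave[i0:i1] <- wave[i0:i1] + seg / max(abs(seg), 1e-9) * 0.5
      out[k, ] <- c(s, s + dur)
    }
    out
  })
  ann <- ann[order(ann[, 1]), , drop = FALSE]
  attr(wave, "annotations") <- ann
  list(wave = wave,
       annotations = data.frame(start_s = ann[, 1], end_s = ann[, 2]))
}

#' Generate a complete synthetic crossover cohort on disk
#'
#' Writes WAV recordings, transcript text files, interviewer annotations
#' (Description task only), a background corpus, the lexicon, a manifest
#' CSV, and a ground-truth JSON with every realized generator parameter.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (data.frame), `truth` (list, one entry per
#'   manifest row), `lexicon`, `corpus`, and the paths written.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sc_cohort_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  lex <- build_lexicon(seed = derive_seed(config$seed, "lex"))
  n_topics <- length(setdiff(unique(lex$topic), c("function", "concept")))
  corpus <- build_corpus(lex, seed = derive_seed(config$seed, "corp"))
  write_lexicon(lex, file.path(out_dir, "lexicon.tsv"))
  writeLines(corpus, file.path(out_dir, "corpus.txt"))
  rows <- list()
  truth <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("S%02d", s)
    prof <- draw_profile(n_topics, derive_seed(config$seed, "prof", sid))
    # randomized condition order (the session sequence) per subject
    cond_order <- with_local_seed(derive_seed(config$seed, "order", sid),
                                  sample(config$conditions))
    for (task in config$tasks) {
      for (cond in config$conditions) {
        session <- which(cond_order == cond)
        eff <- effect_for(config$effect_map, cond)
        key <- paste(sid, cond, task, sep = "_")
        v <- synth_voice(prof, eff, config$duration_s, config$sample_rate,
                         seed = derive_seed(config$seed, "voice", key))
        ann_path <- NA_character_
        if (identical(task, "Description")) {
          ov <- overlay_interviewer(v$wave, config$sample_rate,
                                    v$truth$pause_intervals,
                                    derive_seed(config$seed, "intv", key))
          v$wave <- ov$wave
          ann_path <- file.path(out_dir, paste0(key, "_ann.csv"))
          write.csv(ov$annotations, ann_path, row.names = FALSE)
        }
        audio_path <- file.path(out_dir, paste0(key, ".wav"))
        write_wav(v$wave, config$sample_rate, audio_path)
        w <- min(0.1 + eff$concept_weight, 1)
        txt <- synth_transcript(prof, concept_weight = w, lexicon = lex,
                                seed = derive_seed(config$seed, "text", key),
                                richness = eff$hapax_factor)
        transcript_path <- file.path(out_dir, paste0(key, ".txt"))
        writeLines(txt, transcript_path)
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sid, session = session, condition = cond, task = task,
          audio_path = audio_path, transcript_path = transcript_path,
          annotation_path = ann_path, stringsAsFactors = FALSE)
        truth[[key]] <- c(v$truth,
                          list(concept_weight = w,
                               hapax_factor = eff$hapax_factor,
                               base_f0 = prof$base_f0,
                               base_jitter = prof$base_jitter,
                               base_pause_rate = prof$base_pause_rate,
                               n_tokens = length(strsplit(txt, "\\s+")[[1]])))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    lapply(truth, function(t) {
      t$pause_intervals <- as.data.frame(t$pause_intervals)
      t$utterance_intervals <- as.data.frame(t$utterance_intervals)
      t
    }),
    truth_path, auto_unbox = TRUE, digits = NA)
  list(manifest = manifest, truth = truth, lexicon = lex, corpus = corpus,
       manifest_path = manifest_path, truth_path = truth_path,
       out_dir = out_dir)
}

#' Simulate a cohort feature table directly at the feature level
#'
#' Draws the assembled 126-column feature table from the generator's
#' statistical model (subject baseline + condition effect + session noise)
#' without synthesizing audio or text. This is the instrument for
#' large-scale calibration and power studies: the planted effect is the
#' class-mean shift of the within-subject contrast, in units of the
#' contrast's noise standard deviation.
#'
#' @param n_subjects number of subjects.
#' @param conditions two or more condition labels; the effect is planted on
#'   the first condition relative to the others.
#' @param task task label stamped on every row.
#' @param n_acoustic,n_semantic,n_psycholinguistic features per domain
#'   (defaults 88/21/17).
#' @param effect_size class-mean shift of the contrast, in contrast-noise
#'   standard deviations.
#' @param n_effect_features number of features carrying the effect.
#' @param seed integer seed.
#' @return feature table data.frame (one row per subject x condition) with
#'   attribute `truth` naming the effect features and size.
#' @export
simulate_feature_table <- function(n_subjects = 30,
                                   conditions = c("DRUG", "PBO"),
                                   task = "Monologue",
                                   n_acoustic = 88, n_semantic = 21,
                                   n_psycholinguistic = 17,
                                   effect_size = 0, n_effect_features = 5,
                                   seed = 1) {
  stopifnot(n_subjects >= 2, length(conditions) >= 2, effect_size >= 0)
  feats <- c(sprintf("A-sim%03d", seq_len(n_acoustic)),
             sprintf("S-sim%03d", seq_len(n_semantic)),
             sprintf("P-sim%03d", seq_len(n_psycholinguistic)))
  p <- length(feats)
  with_local_seed(seed, {
    eff_idx <- sample.int(p, min(n_effect_features, p))
    delta <- numeric(p)
    delta[eff_idx] <- effect_size
    rows <- list()
    for (s in seq_len(n_subjects)) {
      base <- rnorm(p)
      for (ci in seq_along(conditions)) {
        x <- base + rnorm(p, sd = 1 / sqrt(2)) +
          if (ci == 1) delta else 0
        rows[[length(rows) + 1]] <- data.frame(
          subject_id = sprintf("S%02d", s), session = ci,
          condition = conditions[ci], task = task,
          t(x), stringsAsFactors = FALSE)
      }
    }
    tab <- do.call(rbind, rows)
    names(tab)[-(1:4)] <- feats
    attr(tab, "truth") <- list(effect_features = feats[eff_idx],
                               effect_size = effect_size)
    tab
  })
}
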