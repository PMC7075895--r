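# End-to-end pipeline: synthesize a cohort, extract all features, run the
# group-level statistics and the nested cross-validated classification,
# and write every artifact plus a human-readable report.

#' Pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort a [cohort_config()] describing the synthetic cohort.
#' @param contrast_pairs list of length-2 character vectors of condition
#'   labels to contrast; defaults to every non-reference condition against
#'   the first (reference) condition.
#' @param classification_task task used for the contrast classification;
#'   defaults to the first task.
#' @param semantic_rank truncation rank of the semantic model.
#' @param fdr_q false-discovery-rate target for the group tests.
#' @param seed seed for the classification stage (cohort synthesis uses
#'   the seed inside `cohort`).
#' @return list of class `sc_pipeline_config`.
#' @export
pipeline_config <- function(out_dir, cohort = cohort_config(),
                            contrast_pairs = NULL,
                            classification_task = cohort$tasks[1],
                            semantic_rank = 100, fdr_q = 0.05, seed = 1) {
  if (is.null(contrast_pairs))
    contrast_pairs <- lapply(cohort$conditions[-1],
                             function(c2) c(c2, cohort$conditions[1]))
  structure(list(out_dir = out_dir, cohort = cohort,
                 contrast_pairs = contrast_pairs,
                 classification_task = classification_task,
                 semantic_rank = semantic_rank, fdr_q = fdr_q, seed = seed),
            class = "sc_pipeline_config")
}

config_digest <- function(config) {
  # hash the scientific configuration only; the output location must not
  # change the digest, otherwise identical runs are not recognized as such
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  digest_text(utils::capture.output(utils::str(
    cfg, give.attr = FALSE, digits.d = 12)))
}

#' Validate a cohort manifest file
#'
#' Checks the manifest schema (required columns), field validity (no
#' missing subject/condition/task labels, numeric sessions, referenced
#' files present), and design completeness (every subject has every
#' condition exactly once per task). All problems are reported together,
#' each prefixed with its CSV line number (header = line 1).
#'
#' @param path manifest CSV path.
#' @return the manifest data.frame, invisibly; errors if invalid.
#' @export
validate_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  m <- read.csv(path, stringsAsFactors = FALSE)
  problems <- character(0)
  need <- c("subject_id", "session", "condition", "task", "audio_path",
            "transcript_path")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0)
    stop("manifest lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (i in seq_len(nrow(m))) {
    ln <- i + 1  # header occupies line 1
    for (col in c("subject_id", "condition", "task"))
      if (is.na(m[[col]][i]) || !nzchar(m[[col]][i]))
        problems <- c(problems, sprintf("line %d: empty %s", ln, col))
    if (is.na(suppressWarnings(as.numeric(m$session[i]))))
      problems <- c(problems, sprintf("line %d: non-numeric session", ln))
    for (col in c("audio_path", "transcript_path")) {
      pth <- m[[col]][i]
      if (!is.na(pth) && nzchar(pth) && !file.exists(pth))
        problems <- c(problems, sprintf("line %d: missing file %s", ln, pth))
    }
  }
  # design completeness: every subject x task must hold each condition once
  conds <- sort(unique(m$condition))
  for (s in unique(m$subject_id)) for (tk in unique(m$task)) {
    have <- m$condition[m$subject_id == s & m$task == tk]
    for (cn in conds) {
      k <- sum(have == cn)
      if (k != 1)
        problems <- c(problems, sprintf(
          "subject %s, task %s: condition %s appears %d times (expected 1)",
          s, tk, cn, k))
    }
  }
  if (length(problems) > 0)
    stop("invalid manifest:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  invisible(m)
}

#' Run the full analysis pipeline
#'
#' Synthesizes the cohort, builds the semantic model from the cohort's
#' background corpus, assembles and imputes the feature table, runs paired
#' Wilcoxon tests with FDR control for every configured contrast, embeds
#' per-condition partial-correlation structure, runs the nested
#' leave-one-participant-out classification where enough subjects are
#' available, and writes all artifacts plus `report.md` into `out_dir`.
#' Unusable recordings are excluded with a warning and the run completes.
#'
#' @param config a [pipeline_config()].
#' @return list of class `sc_pipeline_result`: `feature_table`, `tests`
#'   (per contrast pair), `cv` (per contrast pair or NULL), `mds`,
#'   `paths` of written artifacts, `digest` of the configuration.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "sc_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  cohort <- generate_cohort(config$cohort,
                            file.path(config$out_dir, "cohort"))
  model <- build_semantic_model(cohort$corpus, k = config$semantic_rank)
  freq <- corpus_frequency_table(cohort$corpus)
  table <- assemble_feature_table(cohort$manifest, model, cohort$lexicon,
                                  freq)
  table <- impute_features(table)
  paths$feature_table <- file.path(config$out_dir, "feature_table.csv")
  write_feature_table(table, paths$feature_table)

  # group-level statistics per configured contrast
  tests <- list()
  for (pair in config$contrast_pairs) {
    for (tk in unique(table$task)) {
      wt <- wilcoxon_paired(table, pair[1], pair[2], tk)
      fdr <- bh_fdr(wt$p_value, config$fdr_q)
      wt$p_adjusted <- fdr$adjusted
      wt$reject <- fdr$reject
      key <- paste(pair[1], pair[2], tk, sep = "_")
      p <- file.path(config$out_dir, paste0("tests_", key, ".csv"))
      write.csv(wt, p, row.names = FALSE)
      paths[[paste0("tests_", key)]] <- p
      tests[[key]] <- wt
    }
  }

  # per-condition partial-correlation structure, embedded when >= 3
  # conditions are present
  mds <- NULL
  conds <- unique(table$condition)
  if (length(conds) >= 3 && nrow(table[table$condition == conds[1], ]) >= 3) {
    fc <- feature_columns(table)
    mats <- lapply(conds, function(cn)
      partial_correlations(as.matrix(table[table$condition == cn, fc])))
    names(mats) <- conds
    mds <- mds_embed(mats)
    pm <- data.frame(condition = rownames(mds$points), mds$points)
    paths$mds <- file.path(config$out_dir, "mds.csv")
    write.csv(pm, paths$mds, row.names = FALSE)
  }

  # nested cross-validated contrast classification
  cv <- list()
  weights <- list()
  n_sub <- length(unique(table$subject_id))
  for (pair in config$contrast_pairs) {
    key <- paste(pair[1], pair[2], sep = "_")
    if (n_sub < 3) {
      cv[[key]] <- NULL
      next
    }
    ctr <- make_contrasts(table, pair[1], pair[2],
                          config$classification_task)
    res <- nested_lopo_cv(ctr, seed = derive_seed(config$seed, "cv", key))
    cv[[key]] <- res
    if (length(res$fold_weights) > 0) {
      all_w <- Reduce(`+`, lapply(res$fold_weights, function(w) {
        full <- stats::setNames(numeric(length(ctr$features)), ctr$features)
        full[names(w)] <- abs(w)
        full
      }))
      if (sum(all_w) > 0)
        weights[[key]] <- weight_profile(all_w)
    }
  }
  if (length(cv) > 0) {
    paths$cv <- file.path(config$out_dir, "cv_results.json")
    jsonlite::write_json(
      lapply(cv, function(r) list(accuracy = r$accuracy,
                                  n_correct = r$n_correct,
                                  n_total = r$n_total,
                                  p_value = r$p_value,
                                  folds = r$folds)),
      paths$cv, auto_unbox = TRUE, digits = NA)
  }
  if (length(weights) > 0) {
    wtab <- do.call(rbind, lapply(names(weights), function(k)
      data.frame(contrast = k, feature = names(weights[[k]]),
                 contribution = as.numeric(weights[[k]]))))
    paths$weights <- file.path(config$out_dir, "weights.csv")
    write.csv(wtab, paths$weights, row.names = FALSE)
  }

  digest <- config_digest(config)
  paths$report <- file.path(config$out_dir, "report.md")
  write_report(paths$report, config, digest, table, tests, cv, weights, mds)

  structure(list(feature_table = table, tests = tests, cv = cv, mds = mds,
                 weights = weights, paths = paths, digest = digest),
            class = "sc_pipeline_result")
}

write_report <- function(path, config, digest, table, tests, cv, weights,
                         mds) {
  L <- c("# Speech contrast analysis report", "",
         sprintf("Configuration digest: `%s`", digest),
         sprintf("Subjects: %d; rows: %d; features: %d",
                 length(unique(table$subject_id)), nrow(table),
                 length(feature_columns(table))), "",
         "## Group tests (paired Wilcoxon, BH-FDR)", "")
  for (key in names(tests)) {
    wt <- tests[[key]]
    sig <- wt$feature[wt$reject]
    L <- c(L, sprintf("- %s: %d/%d features significant at q = %g%s",
                      key, length(sig), nrow(wt), config$fdr_q,
                      if (length(sig) > 0 && length(sig) <= 10)
                        paste0(" (", paste(sig, collapse = ", "), ")")
                      else ""))
  }
  L <- c(L, "", "## Contrast classification (nested LOPO CV)", "")
  if (length(cv) == 0) {
    L <- c(L, "- skipped: fewer than 3 subjects available")
  } else for (key in names(cv)) {
    r <- cv[[key]]
    L <- c(L, sprintf("- %s: accuracy %.1f%% (%d/%d), binomial p = %.3g",
                      key, 100 * r$accuracy, r$n_correct, r$n_total,
                      r$p_value))
  }
  if (length(weights) > 0) {
    L <- c(L, "", "## Leading linear-model features (>= 10% contribution)",
           "")
    for (key in names(weights)) {
      w <- weights[[key]]
      lead <- w[w >= attr(w, "display_threshold")]
      lead <- sort(lead, decreasing = TRUE)
      L <- c(L, sprintf("- %s: %s", key, if (length(lead) == 0)
        "none above threshold" else
          paste(sprintf("%s (%.0f%%)", names(lead), 100 * lead),
                collapse = ", ")))
    }
  }
  if (!is.null(mds)) {
    L <- c(L, "", "## Condition correlation-structure embedding", "",
           sprintf("Stress: %.3g", mds$stress),
           utils::capture.output(print(round(mds$points, 4))))
  }
  writeLines(L, path)
  invisible(path)
}
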