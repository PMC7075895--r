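# Cohort feature-table assembly: one row per subject x condition x task,
# 126 named feature columns (88 acoustic, 21 semantic, 17 psycholinguistic)
# with A-/S-/P- domain prefixes.

key_columns <- function() c("subject_id", "session", "condition", "task")

#' Feature-name helpers
#' @param table a feature table.
#' @return character vector of feature column names (or the domain subset).
#' @export
feature_columns <- function(table) setdiff(names(table), key_columns())

#' @rdname feature_columns
#' @param domain one of "acoustic", "semantic", "psycholinguistic".
#' @export
domain_columns <- function(table, domain) {
  pre <- c(acoustic = "A-", semantic = "S-", psycholinguistic = "P-")[[domain]]
  grep(paste0("^", sub("-", "[-]", pre)), feature_columns(table),
       value = TRUE)
}

#' Assemble the cohort feature table from a manifest
#'
#' Runs acoustic and/or text feature extraction for every manifest row.
#' Unusable recordings are skipped with a logged reason; subjects can later
#' be excluded by design-completeness checks.
#'
#' @param manifest manifest data.frame (see [generate_cohort()] for the
#'   schema).
#' @param model `sc_semantic_model` (required for semantic features).
#' @param lexicon `sc_lexicon` used for cleaning/tagging.
#' @param frequency_table reference word counts for the frequency feature.
#' @param domains subset of c("acoustic", "semantic", "psycholinguistic").
#' @return data.frame: key columns plus prefixed feature columns.
#' @export
assemble_feature_table <- function(manifest, model = NULL, lexicon = NULL,
                                   frequency_table = NULL,
                                   domains = c("acoustic", "semantic",
                                               "psycholinguistic")) {
  domains <- match.arg(domains, several.ok = TRUE)
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    feats <- numeric(0)
    if ("acoustic" %in% domains) {
      av <- extract_acoustic_record(rec)
      if (is.null(av)) next
      names(av) <- paste0("A-", names(av))
      feats <- c(feats, av)
    }
    if (any(c("semantic", "psycholinguistic") %in% domains)) {
      txt <- tryCatch(readLines(rec$transcript_path, warn = FALSE),
                      error = function(e) e)
      if (inherits(txt, "error")) {
        warning("record skipped (unreadable transcript ",
                rec$transcript_path, ")", call. = FALSE)
        next
      }
      tr <- clean_and_tag(txt, lexicon)
      if ("semantic" %in% domains)
        feats <- c(feats, extract_semantic(tr, model))
      if ("psycholinguistic" %in% domains)
        feats <- c(feats, extract_psycholinguistic(tr, frequency_table))
    }
    rows[[length(rows) + 1]] <- cbind(rec[key_columns()],
                                      as.data.frame(t(feats)))
  }
  if (length(rows) == 0) stop("no usable records in manifest", call. = FALSE)
  out <- do.call(rbind, rows)
  names(out) <- c(key_columns(), names(rows[[1]])[-(1:4)])
  rownames(out) <- NULL
  out
}

#' Impute missing feature values with the cohort median
#'
#' Applied at table-assembly time only; a companion logical missingness
#' mask is attached as attribute `missing_mask`.
#'
#' @param table feature table.
#' @return table with NAs replaced by per-column medians.
#' @export
impute_features <- function(table) {
  fc <- feature_columns(table)
  mask <- is.na(as.matrix(table[fc]))
  for (f in fc) {
    v <- table[[f]]
    if (anyNA(v)) {
      med <- stats::median(v, na.rm = TRUE)
      if (is.na(med)) med <- 0
      table[[f]][is.na(v)] <- med
    }
  }
  attr(table, "missing_mask") <- mask
  table
}

#' Read/write the cohort feature table CSV
#' @param table feature table.
#' @param path CSV path.
#' @return `path` / the table.
#' @export
write_feature_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out
}
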