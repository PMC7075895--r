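# Synthetic transcript generation.
#
# Transcripts are token streams from a mixture of the subject's preferred
# background topics and the concept-neighbourhood topic; the mixture weight
# is the planted "semantic content" effect. Function words, fillers,
# punctuation and an occasional special character are interleaved so that
# the cleaning and tagging stages are genuinely exercised.

#' Generate one synthetic transcript
#'
#' @param profile a [subject_profile()]; `verbosity` sets the expected
#'   content-token count and `topic_preference` the background topic mix.
#' @param concept_weight mixture weight in \[0, 1\] toward the concept
#'   topic; higher values pull the text semantically closer to the concept
#'   words.
#' @param lexicon from [build_lexicon()].
#' @param seed integer seed.
#' @param richness vocabulary-richness (hapax) factor; values above 1
#'   flatten the word distributions, producing more distinct and
#'   once-occurring words.
#' @return a single string.
#' @export
synth_transcript <- function(profile, concept_weight = 0, lexicon,
                             seed = 1, richness = 1) {
  stopifnot(richness > 0)
  if (!is.numeric(concept_weight) || concept_weight < 0 || concept_weight > 1)
    stop("concept_weight must lie in [0, 1]", call. = FALSE)
  topics <- setdiff(unique(lexicon$topic), c("function", "concept"))
  if (length(topics) == 0) stop("lexicon has no background topics",
                                call. = FALSE)
  pref <- profile$topic_preference
  if (is.null(pref)) pref <- rep(1 / length(topics), length(topics))
  if (length(pref) != length(topics))
    stop("topic_preference length must match number of background topics",
         call. = FALSE)
  dists <- lapply(c(topics, "concept"), topic_distribution, lexicon = lexicon)
  names(dists) <- c(topics, "concept")
  dists <- lapply(dists, function(d) d^(1 / richness) / sum(d^(1 / richness)))
  if (any(vapply(dists, length, integer(1)) == 0))
    stop("empty topic distribution in lexicon", call. = FALSE)
  fw <- lexicon[lexicon$topic == "function" & !lexicon$filler, "word"]
  fillers <- lexicon$word[lexicon$filler]
  with_local_seed(seed, {
    n <- max(20, rpois(1, profile$verbosity))
    pick_concept <- runif(n) < concept_weight
    toks <- character(n)
    for (i in seq_len(n)) {
      d <- if (pick_concept[i]) dists[["concept"]] else
        dists[[sample(topics, 1, prob = pref)]]
      toks[i] <- sample(names(d), 1, prob = d)
    }
    # interleave function words before ~40% of content tokens
    out <- character(0)
    sent_len <- 0
    for (i in seq_len(n)) {
      if (runif(1) < 0.4) out <- c(out, sample(fw, 1))
      if (runif(1) < 0.03) out <- c(out, sample(fillers, 1))
      out <- c(out, toks[i])
      sent_len <- sent_len + 1
      if (sent_len >= sample(6:14, 1)) {
        out[length(out)] <- paste0(out[length(out)],
                                   sample(c(".", ".", "!", "?"), 1))
        sent_len <- 0
      } else if (runif(1) < 0.05) {
        out[length(out)] <- paste0(out[length(out)], ",")
      }
    }
    if (runif(1) < 0.5) out <- c(out, "#")   # special character, cleaned later
    paste(out, collapse = " ")
  })
}
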