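# Synthetic-English lexicon and background corpus.
#
# The generator speaks a closed synthetic language: pseudoword content
# vocabulary partitioned into topics, plus real English function words,
# fillers, and the 21 concept words of interest. Shipping the language as a
# seeded builder (rather than a data file) keeps the package text-only while
# giving the cleaning, tagging, lemmatization, and LSA stages realistic
# structure to work on.

#' Default concept-of-interest words
#'
#' The 21 mental-state concepts whose semantic proximity to each transcript
#' is measured.
#'
#' @return character vector of length 21.
#' @export
default_concepts <- function() {
  c("affect", "anxiety", "compassion", "confidence", "disdain", "emotion",
    "empathy", "fear", "feeling", "forgive", "friend", "happy", "intimacy",
    "love", "pain", "peace", "rapport", "sad", "support", "think", "talk")
}

# POS of each concept word in the packaged lexicon
concept_pos <- function() {
  pos <- rep("NN", 21)
  names(pos) <- default_concepts()
  pos[c("forgive", "think", "talk")] <- "VB"
  pos[c("happy", "sad")] <- "JJ"
  pos
}

# Deterministic pool of distinct pronounceable pseudowords.
pseudoword_pool <- function(n) {
  on1 <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v",
           "z", "br", "dr", "gr", "kl", "pl", "st", "tr", "sh", "ch")
  nuc <- c("a", "e", "i", "o", "u", "ai", "ea", "ou")
  cod <- c("", "n", "r", "l", "s", "t", "m", "k")
  syl <- as.vector(outer(as.vector(outer(on1, nuc, paste0)), cod, paste0))
  two <- as.vector(outer(syl, syl, paste0))
  if (n > length(two)) stop("pseudoword pool exhausted", call. = FALSE)
  # deterministic interleave independent of RNG
  idx <- (seq_len(n) * 7919L) %% length(two) + 1L
  while (anyDuplicated(idx)) {         # resolve rare collisions
    dup <- which(duplicated(idx))
    idx[dup] <- (idx[dup] + seq_along(dup)) %% length(two) + 1L
  }
  two[idx]
}

function_word_table <- function() {
  fw <- rbind(
    data.frame(word = c("the", "this", "that", "these", "those"),
               pos = "DT", stringsAsFactors = FALSE),
    data.frame(word = c("a", "an", "some", "any", "each", "every", "no"),
               pos = "DT", stringsAsFactors = FALSE),
    data.frame(word = c("i", "you", "he", "she", "it", "we", "they", "me",
                        "him", "her", "us", "them", "my", "your", "his",
                        "its", "our", "their"),
               pos = "PRP", stringsAsFactors = FALSE),
    data.frame(word = c("of", "in", "on", "at", "by", "with", "from", "to",
                        "for", "about", "over", "under", "into", "through",
                        "after", "before", "between", "during"),
               pos = "IN", stringsAsFactors = FALSE),
    data.frame(word = c("and", "or", "but", "so", "because", "if", "when",
                        "while", "although"),
               pos = "CC", stringsAsFactors = FALSE),
    data.frame(word = c("is", "am", "are", "was", "were", "be", "been",
                        "being", "have", "has", "had", "do", "does", "did",
                        "will", "would", "can", "could", "may", "might",
                        "shall", "should", "must"),
               pos = "AUX", stringsAsFactors = FALSE),
    data.frame(word = c("um", "uh", "er", "hmm", "like"),
               pos = "UH", stringsAsFactors = FALSE),
    data.frame(word = c("not", "very", "really", "just", "then", "there",
                        "here", "now", "also"),
               pos = "RB", stringsAsFactors = FALSE)
  )
  fw$lemma <- fw$word
  # auxiliary lemmas
  fw$lemma[fw$word %in% c("is", "am", "are", "was", "were", "been", "being")] <- "be"
  fw$lemma[fw$word %in% c("has", "had")] <- "have"
  fw$lemma[fw$word %in% c("does", "did")] <- "do"
  fw$topic <- "function"
  fw$filler <- fw$pos == "UH"
  fw
}

#' Build the packaged synthetic lexicon
#'
#' Produces the closed vocabulary the synthetic cohort speaks: pseudoword
#' nouns/verbs/adjectives/adverbs (with inflected variants) partitioned into
#' topics, a dedicated concept topic containing the 21 concept words plus
#' pseudoword neighbours, and English function words, auxiliaries, and
#' fillers with fixed Penn-Treebank-style tags.
#'
#' @param n_topics number of background content topics (excluding the
#'   concept topic).
#' @param seed integer seed; the lexicon is fully determined by it.
#' @return data.frame with columns `word`, `pos`, `lemma`, `topic`,
#'   `filler`, of class `sc_lexicon`.
#' @export
build_lexicon <- function(n_topics = 7, seed = 42) {
  stopifnot(n_topics >= 1)
  with_local_seed(derive_seed(seed, "lexicon"), {
    per_topic <- c(nouns = 55, verbs = 18, adjs = 14, advs = 8)
    n_needed <- (n_topics + 1) * sum(per_topic) + 40
    pool <- pseudoword_pool(n_needed)
    take <- local({
      i <- 0
      function(n) {
        out <- pool[(i + 1):(i + n)]
        i <<- i + n
        out
      }
    })
    inflect <- function(base, pos) {
      switch(pos,
        NN = data.frame(word = c(base, paste0(base, "s")), pos = c("NN", "NNS"),
                        lemma = base, stringsAsFactors = FALSE),
        VB = data.frame(word = c(base, paste0(base, "s"), paste0(base, "ed"),
                                 paste0(base, "ing")),
                        pos = c("VB", "VBZ", "VBD", "VBG"),
                        lemma = base, stringsAsFactors = FALSE),
        JJ = data.frame(word = base, pos = "JJ", lemma = base,
                        stringsAsFactors = FALSE),
        RB = data.frame(word = paste0(base, "ly"), pos = "RB", lemma = base,
                        stringsAsFactors = FALSE))
    }
    topic_block <- function(topic, n_extra_nouns = 0) {
      blocks <- list()
      for (spec in list(c("NN", per_topic[["nouns"]] + n_extra_nouns),
                        c("VB", per_topic[["verbs"]]),
                        c("JJ", per_topic[["adjs"]]),
                        c("RB", per_topic[["advs"]]))) {
        bases <- take(as.integer(spec[2]))
        blocks <- c(blocks, lapply(bases, inflect, pos = spec[1]))
      }
      out <- do.call(rbind, blocks)
      out$topic <- topic
      out
    }
    content <- do.call(rbind, lapply(seq_len(n_topics), function(t)
      topic_block(paste0("topic", t))))
    concept_block <- topic_block("concept", n_extra_nouns = -20)
    cw <- concept_pos()
    cw_rows <- do.call(rbind, lapply(names(cw), inflect2 <- function(w)
      inflect(w, cw[[w]])))
    cw_rows$topic <- "concept"
    content <- rbind(content, concept_block, cw_rows)
    content$filler <- FALSE
    lex <- rbind(function_word_table(), content)
    # a few irregular verbs so the lemmatizer's lookup path is exercised
    irr <- data.frame(word = c("ran", "ate", "dogs", "dog", "run", "eat"),
                      pos = c("VBD", "VBD", "NNS", "NN", "VB", "VB"),
                      lemma = c("run", "eat", "dog", "dog", "run", "eat"),
                      topic = "topic1", filler = FALSE,
                      stringsAsFactors = FALSE)
    lex <- rbind(lex, irr)
    lex <- lex[!duplicated(lex$word), ]
    rownames(lex) <- NULL
    class(lex) <- c("sc_lexicon", "data.frame")
    lex
  })
}

#' Write / read a lexicon as TSV
#' @param lexicon an `sc_lexicon` data.frame.
#' @param path TSV file path.
#' @return `path` (write) or the lexicon (read).
#' @export
write_lexicon <- function(lexicon, path) {
  utils::write.table(lexicon, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_lexicon
#' @export
read_lexicon <- function(path) {
  lex <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(lex) <- c("sc_lexicon", "data.frame")
  lex
}

# Zipf-weighted sampling distribution over the word forms of one topic.
topic_distribution <- function(lexicon, topic) {
  words <- lexicon$word[lexicon$topic == topic]
  w <- 1 / seq_along(words)^0.8
  stats::setNames(w / sum(w), words)
}

#' Build the packaged background corpus
#'
#' Generates a seed-fixed document collection from the same topic model the
#' transcript generator uses; it plays the role an external reference corpus
#' would play for the semantic embedding.
#'
#' @param lexicon from [build_lexicon()].
#' @param n_docs number of documents.
#' @param doc_len expected tokens per document.
#' @param seed integer seed.
#' @return character vector of documents (one string each).
#' @export
build_corpus <- function(lexicon, n_docs = 500, doc_len = 200, seed = 42) {
  stopifnot(n_docs >= 1, doc_len >= 10)
  topics <- setdiff(unique(lexicon$topic), "function")
  dists <- lapply(topics, topic_distribution, lexicon = lexicon)
  names(dists) <- topics
  fw <- lexicon[lexicon$topic == "function" & !lexicon$filler, ]
  with_local_seed(derive_seed(seed, "corpus"), {
    vapply(seq_len(n_docs), function(d) {
      topic <- topics[(d - 1) %% length(topics) + 1]
      n <- max(10, rpois(1, doc_len))
      n_fun <- rbinom(1, n, 0.3)
      dd <- dists[[topic]]
      toks <- c(sample(names(dd), n - n_fun, replace = TRUE, prob = dd),
                sample(fw$word, n_fun, replace = TRUE))
      paste(sample(toks), collapse = " ")
    }, character(1))
  })
}

#' Word-frequency table from a corpus
#'
#' Token counts over a document collection; used for the mean log-frequency
#' lexical feature.
#'
#' @param corpus character vector of documents.
#' @return named integer vector of token counts.
#' @export
corpus_frequency_table <- function(corpus) {
  toks <- unlist(strsplit(tolower(paste(corpus, collapse = " ")), "\\s+"))
  toks <- toks[nzchar(toks)]
  table(toks)
}
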