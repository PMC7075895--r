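# Psycholinguistic features: propositional idea density, POS ratios, and
# lexical-richness statistics.

aux_words <- function() c("is", "am", "are", "was", "were", "be", "been",
                          "being", "have", "has", "had", "do", "does",
                          "did", "will", "would", "can", "could", "may",
                          "might", "shall", "should", "must")

indefinite_words <- function() c("a", "an", "some", "any", "each", "every",
                                 "no", "another", "other", "either",
                                 "neither")

definite_words <- function() c("the", "this", "that", "these", "those")

is_verb_tag <- function(tags) startsWith(tags, "V") | tags == "AUX" |
  tags == "MD"

#' Count expressed propositions (idea units)
#'
#' Propositional-idea counting by POS class: verbs, adjectives, adverbs,
#' prepositions, and conjunctions each contribute one idea, with two
#' adjustment rules — an auxiliary immediately preceding a verb is not
#' counted, and determiners never count. This is a deliberate
#' approximation to full propositional-idea raters, carrying their two
#' highest-impact rules.
#'
#' @param transcript an `sc_transcript`.
#' @return integer idea count.
#' @export
count_propositions <- function(transcript) {
  tags <- transcript$tags
  toks <- transcript$tokens
  n <- length(tags)
  if (n == 0) return(0L)
  counts <- is_verb_tag(tags) | startsWith(tags, "JJ") |
    startsWith(tags, "RB") | tags == "IN" | tags == "CC"
  counts[tags == "DT"] <- FALSE
  # auxiliary immediately before a verb does not count
  if (n > 1) {
    aux_here <- (toks %in% aux_words()) | tags == "AUX"
    before_verb <- c(is_verb_tag(tags[-1]), FALSE)
    counts[aux_here & before_verb] <- FALSE
  }
  as.integer(sum(counts))
}

#' Lexical profile of a transcript
#'
#' Computes token/type/hapax counts and the derived richness statistics:
#' Honoré's R = 100 log(N) / (1 - V1/V) (undefined when every type is a
#' hapax) and Brunet's W = N^(V^-0.165), plus content/empty word counts,
#' filler count, and mean log word frequency against a reference table.
#'
#' @param transcript an `sc_transcript`.
#' @param frequency_table named counts (from [corpus_frequency_table()]);
#'   NULL drops the frequency feature.
#' @return list of class `sc_lexical_profile` with fields `N`, `V`, `V1`,
#'   `ideas`, `density`, `honore`, `brunet`, `pos_counts`,
#'   `content_words`, `empty_words`, `fillers`, `mean_log_freq`.
#' @export
lexical_stats <- function(transcript, frequency_table = NULL) {
  toks <- transcript$tokens
  tags <- transcript$tags
  N <- length(toks)
  stopifnot(N >= 1)
  tab <- table(toks)
  V <- length(tab)
  V1 <- sum(tab == 1)
  honore <- if (V1 == V) {
    warning("Honore's statistic undefined: every type is a hapax",
            call. = FALSE)
    NA_real_
  } else 100 * log(N) / (1 - V1 / V)
  brunet <- N^(V^-0.165)
  ideas <- count_propositions(transcript)
  content <- sum(startsWith(tags, "NN") | is_verb_tag(tags) |
                 startsWith(tags, "JJ") | startsWith(tags, "RB"))
  pos_counts <- c(
    pronouns = sum(tags %in% c("PRP", "PRP$")),
    nouns = sum(startsWith(tags, "NN")),
    verbs = sum(is_verb_tag(tags)),
    determiners = sum(tags == "DT"),
    indefinites = sum(toks %in% indefinite_words()),
    definites = sum(toks %in% definite_words()),
    i = sum(toks == "i"))
  mean_log_freq <- if (is.null(frequency_table)) NA_real_ else {
    cnt <- as.numeric(frequency_table[toks])
    cnt[is.na(cnt)] <- 0
    mean(log1p(cnt))
  }
  structure(list(N = N, V = V, V1 = V1, ideas = ideas, density = ideas / N,
                 honore = honore, brunet = brunet, pos_counts = pos_counts,
                 content_words = content, empty_words = N - content,
                 fillers = sum(transcript$fillers),
                 mean_log_freq = mean_log_freq),
            class = "sc_lexical_profile")
}

#' Extract the 17 psycholinguistic features
#'
#' Idea count, total words, and propositional density; part-of-speech
#' ratios (per total words) for pronouns, nouns, verbs, determiners,
#' indefinites, definites, and the token "i"; Honoré's statistic, Brunet's
#' index, content- and empty-word ratios, type-token ratio, mean log word
#' frequency, and filler ratio.
#'
#' @param transcript an `sc_transcript`.
#' @param frequency_table see [lexical_stats()].
#' @return named numeric vector of 17 features, names prefixed `P-`.
#' @export
extract_psycholinguistic <- function(transcript, frequency_table = NULL) {
  lp <- lexical_stats(transcript, frequency_table)
  N <- lp$N
  c("P-Ideas" = lp$ideas,
    "P-WTotal" = N,
    "P-Density" = lp$density,
    "P-Pronouns" = unname(lp$pos_counts["pronouns"]) / N,
    "P-Nouns" = unname(lp$pos_counts["nouns"]) / N,
    "P-Verbs" = unname(lp$pos_counts["verbs"]) / N,
    "P-Determiners" = unname(lp$pos_counts["determiners"]) / N,
    "P-Indefinites" = unname(lp$pos_counts["indefinites"]) / N,
    "P-Definites" = unname(lp$pos_counts["definites"]) / N,
    "P-I" = unname(lp$pos_counts["i"]) / N,
    "P-Honore" = lp$honore,
    "P-Brunet" = lp$brunet,
    "P-WContent" = lp$content_words / N,
    "P-WEmpty" = lp$empty_words / N,
    "P-TypeToken" = lp$V / N,
    "P-Frequency" = lp$mean_log_freq,
    "P-Fillers" = lp$fillers / N)
}
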