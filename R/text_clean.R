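# Transcript cleaning, tokenization, POS tagging, and lemmatization.

#' Clean, tokenize, tag, and lemmatize a transcript
#'
#' Lowercases, strips punctuation and special characters, tokenizes on
#' whitespace, then assigns Penn-Treebank-style POS tags and lemmas by
#' lexicon lookup with suffix-rule fallback (plural -s, -es/-ies, verbal
#' -ing/-ed/-s, adverbial -ly). Words unknown to the lexicon default to
#' noun (NN).
#'
#' @param text raw transcript string(s).
#' @param lexicon an `sc_lexicon` from [build_lexicon()] (or a compatible
#'   data.frame with `word`, `pos`, `lemma`, `filler`).
#' @return list of class `sc_transcript`: `tokens`, `tags`, `lemmas`
#'   (aligned character vectors), `fillers` (logical).
#' @export
clean_and_tag <- function(text, lexicon) {
  txt <- tolower(paste(text, collapse = " "))
  txt <- gsub("[^a-z' ]", " ", txt)
  toks <- strsplit(trimws(gsub(" +", " ", txt)), " ")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0)
    stop("transcript is empty after cleaning", call. = FALSE)
  idx <- match(toks, lexicon$word)
  tags <- lexicon$pos[idx]
  lemmas <- lexicon$lemma[idx]
  fillers <- lexicon$filler[idx]
  fillers[is.na(fillers)] <- FALSE
  unk <- which(is.na(idx))
  for (i in unk) {
    g <- guess_word(toks[i], lexicon)
    tags[i] <- g$pos
    lemmas[i] <- g$lemma
  }
  structure(list(tokens = toks, tags = tags, lemmas = lemmas,
                 fillers = fillers), class = "sc_transcript")
}

# Suffix-rule fallback for out-of-lexicon words: try to reduce to a known
# lemma; otherwise tag from the suffix shape alone.
guess_word <- function(w, lexicon) {
  known <- function(cand) {
    j <- match(cand, lexicon$lemma)
    if (!is.na(j)) return(cand)
    j <- match(cand, lexicon$word)
    if (!is.na(j)) return(lexicon$lemma[j])
    NA_character_
  }
  rules <- list(
    list(suf = "ies$", rep = "y", pos = "NNS"),
    list(suf = "ing$", rep = "", pos = "VBG"),
    list(suf = "ing$", rep = "e", pos = "VBG"),
    list(suf = "ed$", rep = "", pos = "VBD"),
    list(suf = "ed$", rep = "e", pos = "VBD"),
    list(suf = "ly$", rep = "", pos = "RB"),
    list(suf = "es$", rep = "", pos = "NNS"),
    list(suf = "s$", rep = "", pos = "NNS")
  )
  for (r in rules) {
    if (grepl(r$suf, w)) {
      cand <- sub(r$suf, r$rep, w)
      if (nchar(cand) >= 2) {
        lem <- known(cand)
        if (!is.na(lem)) return(list(pos = r$pos, lemma = lem))
      }
    }
  }
  # shape-only fallback
  if (grepl("ly$", w)) return(list(pos = "RB", lemma = sub("ly$", "", w)))
  if (grepl("ing$", w)) return(list(pos = "VBG", lemma = sub("ing$", "", w)))
  if (grepl("ed$", w)) return(list(pos = "VBD", lemma = sub("ed$", "", w)))
  if (grepl("s$", w) && nchar(w) > 3)
    return(list(pos = "NNS", lemma = sub("s$", "", w)))
  list(pos = "NN", lemma = w)
}
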