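# Transcript cleaning, semantic model, and psycholinguistic features.

test_that("clean_and_tag strips punctuation/special characters and lemmatizes", {
  lex <- fix_lexicon()
  tr <- clean_and_tag("I love my friend!! #blessed", lex)
  expect_equal(tr$tokens, c("i", "love", "my", "friend", "blessed"))
  tr2 <- clean_and_tag("dogs ran", lex)
  expect_equal(tr2$lemmas, c("dog", "run"))
  expect_error(clean_and_tag("!!! ##", lex), "empty")
})

test_that("count_propositions applies the POS-class and adjustment rules", {
  # "the tall man ran quickly": DT JJ NN VBD RB -> JJ + VBD + RB = 3
  t1 <- make_transcript(c("the", "tall", "man", "ran", "quickly"),
                        c("DT", "JJ", "NN", "VBD", "RB"))
  expect_equal(count_propositions(t1), 3L)
  expect_equal(lexical_stats(t1)$density, 0.6)
  # auxiliary immediately before a verb is not counted
  t2 <- make_transcript(c("is", "running"), c("AUX", "VBG"))
  expect_equal(count_propositions(t2), 1L)
  # all nouns: zero ideas; determiners never count
  t3 <- make_transcript(c("man", "dog", "tree"), c("NN", "NN", "NN"))
  expect_equal(count_propositions(t3), 0L)
  t4 <- make_transcript(c("the", "the"), c("DT", "DT"))
  expect_equal(count_propositions(t4), 0L)
})

test_that("Honore and Brunet match the hand computations", {
  # N = 10, V = 7, V1 = 5: a a b b b c d e f g
  toks <- c("a", "a", "b", "b", "b", "c", "d", "e", "f", "g")
  tr <- make_transcript(toks, rep("NN", 10))
  ls <- lexical_stats(tr)
  expect_equal(ls$N, 10)
  expect_equal(ls$V, 7)
  expect_equal(ls$V1, 5)
  expect_equal(ls$honore, 100 * log(10) / (1 - 5 / 7), tolerance = 1e-9)
  expect_equal(round(ls$honore, 1), 805.9)
  # N = 100, V = 50 (every type twice)
  toks2 <- rep(sprintf("w%02d", 1:50), each = 2)
  ls2 <- lexical_stats(make_transcript(toks2, rep("NN", 100)))
  expect_equal(ls2$brunet, 100^(50^-0.165), tolerance = 1e-9)
  expect_equal(round(ls2$brunet, 2), 11.19)
  # every type a hapax: Honore undefined
  expect_warning(
    ls3 <- lexical_stats(make_transcript(letters[1:5], rep("NN", 5))),
    "Honore")
  expect_true(is.na(ls3$honore))
})

test_that("extract_psycholinguistic emits exactly 17 well-defined features", {
  toks <- c("i", "love", "my", "big", "dog", "and", "the", "small", "cat",
            "happily")
  tags <- c("PRP", "VB", "PRP", "JJ", "NN", "CC", "DT", "JJ", "NN", "RB")
  tr <- make_transcript(toks, tags)
  ps <- extract_psycholinguistic(tr)
  expect_length(ps, 17)
  expect_true(all(startsWith(names(ps), "P-")))
  expect_equal(unname(ps["P-Nouns"]), 0.2)        # 2 nouns in 10 tokens
  expect_equal(unname(ps["P-Determiners"]), 0.1)
  expect_equal(unname(ps["P-I"]), 0.1)
  ratios <- ps[c("P-Pronouns", "P-Nouns", "P-Verbs", "P-Determiners",
                 "P-Indefinites", "P-Definites", "P-I", "P-WContent",
                 "P-WEmpty", "P-TypeToken", "P-Fillers")]
  expect_true(all(ratios >= 0 & ratios <= 1))
  # duplication: N doubles, density unchanged, type-token halves
  tr2 <- make_transcript(c(toks, toks), c(tags, tags))
  ps2 <- extract_psycholinguistic(tr2)
  expect_equal(unname(ps2["P-WTotal"]), 20)
  expect_equal(unname(ps2["P-TypeToken"]), unname(ps["P-TypeToken"]) / 2)
})

test_that("build_semantic_model validates input and is deterministic", {
  expect_error(build_semantic_model(fix_corpus()[1:10]), "50")
  expect_error(build_semantic_model(fix_corpus(), k = 100,
                                    concepts = c("love", "zzzznotaword")),
               "zzzznotaword")
  # 150 documents is the smallest round subset of the fixture corpus in
  # which every default concept clears the min_count threshold
  m1 <- build_semantic_model(fix_corpus()[1:150], k = 20)
  m2 <- build_semantic_model(fix_corpus()[1:150], k = 20)
  expect_identical(m1$vectors, m2$vectors)
  expect_equal(m1$k, 20)
})

test_that("proximity is a cosine: identity, symmetry, bounds, OOV error", {
  m <- fix_model()
  w1 <- default_concepts()[1]
  w2 <- default_concepts()[2]
  expect_equal(proximity(m, w1, w1), 1)
  expect_equal(proximity(m, w1, w2), proximity(m, w2, w1))
  expect_true(abs(proximity(m, w1, w2)) <= 1)
  expect_error(proximity(m, w1, "zzzznotaword"), "zzzznotaword")
})

test_that("disjoint-vocabulary documents separate; shared documents cohere", {
  set.seed(3)
  docs <- c(replicate(30, paste(sample(c("alpha", "beta", "gamma"), 30,
                                       replace = TRUE), collapse = " ")),
            replicate(30, paste(sample(c("delta", "epsilon", "zeta"), 30,
                                       replace = TRUE), collapse = " ")))
  m <- build_semantic_model(docs, k = 2, concepts = c("alpha", "delta"))
  expect_gt(proximity(m, "alpha", "beta"), 0.9)
  expect_lt(abs(proximity(m, "alpha", "delta")), 0.1)
})

test_that("full-rank LSA proximities equal brute-force cosines of weighted rows", {
  set.seed(4)
  vocab <- c("love", letters[1:6])
  docs <- vapply(1:60, function(d)
    paste(sample(vocab, 25, replace = TRUE), collapse = " "), character(1))
  m <- build_semantic_model(docs, k = "full", concepts = "love",
                            min_count = 1)
  # brute-force log-entropy weighted term-document matrix
  toks <- strsplit(docs, " ")
  tdm <- vapply(toks, function(tt)
    as.integer(table(factor(tt, levels = m$vocab))),
    integer(length(m$vocab)))
  P <- tdm / rowSums(tdm)
  ent <- rowSums(ifelse(P > 0, P * log(P), 0)) / log(length(docs))
  W <- (1 + ent) * log1p(tdm)
  cosine <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  for (pair in list(c("love", "a"), c("b", "c"), c("d", "love"))) {
    i <- match(pair[1], m$vocab); j <- match(pair[2], m$vocab)
    expect_equal(proximity(m, pair[1], pair[2]), cosine(W[i, ], W[j, ]),
                 tolerance = 1e-8)
  }
})

test_that("extract_semantic emits 21 bounded features and handles OOV text", {
  m <- fix_model()
  lex <- fix_lexicon()
  tr <- clean_and_tag(synth_transcript(subject_profile(), 0.3, lex, seed = 5),
                      lex)
  s <- extract_semantic(tr, m)
  expect_length(s, 21)
  expect_identical(names(s), paste0("S-", default_concepts()))
  expect_true(all(s >= -1 & s <= 1, na.rm = TRUE))
  # median rule on a crafted three-word text
  idx_words <- tr$lemmas[!is.na(match(tr$lemmas, m$vocab))][1:3]
  tr3 <- make_transcript(idx_words, rep("NN", 3), lemmas = idx_words)
  s3 <- extract_semantic(tr3, m, concepts = "love")
  expect_equal(unname(s3),
               median(vapply(idx_words, function(w) proximity(m, "love", w),
                             numeric(1))))
  # no in-vocabulary lemmas: all missing, with a warning
  oov <- make_transcript("qqqq", "NN")
  expect_warning(so <- extract_semantic(oov, m), "in-vocabulary")
  expect_true(all(is.na(so)))
  expect_length(so, 21)
})

test_that("semantic and lexical features are token-order invariant", {
  m <- fix_model()
  lex <- fix_lexicon()
  tr <- clean_and_tag(synth_transcript(subject_profile(), 0.2, lex, seed = 6),
                      lex)
  set.seed(7)
  perm <- sample(length(tr$tokens))
  trp <- make_transcript(tr$tokens[perm], tr$tags[perm], tr$lemmas[perm],
                         tr$fillers[perm])
  expect_equal(extract_semantic(trp, m), extract_semantic(tr, m))
  a <- lexical_stats(tr); b <- lexical_stats(trp)
  expect_equal(b$N, a$N); expect_equal(b$V, a$V); expect_equal(b$V1, a$V1)
  expect_equal(b$honore, a$honore)
})
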