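lex <- example_lexicon()

tagged_quad <- function(effective, affected, relation, polarity,
                        confidence = 1) {
  quad(effective, affected, relation, polarity = polarity) |>
    dplyr::mutate(pol_source = "domain_kb", confidence = confidence)
}

test_that("the OpinionKB deduplicates and resolves polarity conflicts by confidence", {
  quads <- dplyr::bind_rows(
    tagged_quad("cipro", "insomnia", "cause", "negative"),
    tagged_quad("cipro", "insomnia", "cause", "negative"),
    tagged_quad("oracea", "yeast-infection", "rid", "positive")
  )
  kb <- build_opinion_kb(quads)
  expect_equal(nrow(kb), 2)
  expect_equal(kb$support[kb$effective == "cipro"], 2L)
  # higher-confidence polarity wins a key collision
  quads2 <- dplyr::bind_rows(
    tagged_quad("avita", "redness", "cause", "positive", confidence = 1),
    tagged_quad("avita", "redness", "cause", "negative", confidence = 0.6)
  )
  kb2 <- build_opinion_kb(quads2)
  expect_equal(kb2$polarity, "positive")
  # exact confidence ties drop the key
  quads3 <- dplyr::bind_rows(
    tagged_quad("avita", "redness", "cause", "positive", confidence = 0.8),
    tagged_quad("avita", "redness", "cause", "negative", confidence = 0.8)
  )
  kb3 <- build_opinion_kb(quads3)
  expect_equal(nrow(kb3), 0)
  expect_equal(nrow(attr(kb3, "dropped")), 1)
  # contract: polarity-null input errors; empty input is fine
  expect_error(build_opinion_kb(quad("a", "b", "c")), "polarity-tagged")
  expect_equal(nrow(build_opinion_kb(quads[0, ])), 0)
})

test_that("pattern mining keeps combinations supported by more than the threshold", {
  four <- dplyr::bind_rows(purrr::map(
    c("acne", "pain", "insomnia", "confusion"),
    \(e) tagged_quad("accutane", e, "reduce", "positive")
  ))
  # four DISO-typed entries of different types; at type level each (phsu, ty,
  # reduce) has support 1, at group level (CHEM, DISO, reduce) would have 4 --
  # but group patterns build on *retained* type patterns only
  p0 <- mine_patterns(build_opinion_kb(four), lex)
  expect_equal(nrow(p0), 0)
  # four entries reducing to the same type pattern: retained with support 4
  same_type <- dplyr::bind_rows(purrr::map(
    c("pain", "insomnia", "muscle weakness", "skin irritation"),
    \(e) tagged_quad("accutane", e, "reduce", "positive")
  ))
  p4 <- mine_patterns(build_opinion_kb(same_type), lex)
  tp <- p4[p4$level == "type", ]
  expect_equal(nrow(tp), 1)
  expect_equal(tp$effective_code, "phsu")
  expect_equal(tp$affected_code, "sosy")
  expect_equal(tp$support, 4L)
  gp <- p4[p4$level == "group", ]
  expect_equal(nrow(gp), 1)
  expect_equal(gp$affected_code, "DISO")
  # exactly 3 entries: dropped (strict > 3)
  three <- dplyr::bind_rows(purrr::map(
    c("pain", "insomnia", "muscle weakness"),
    \(e) tagged_quad("accutane", e, "reduce", "positive")
  ))
  expect_equal(nrow(mine_patterns(build_opinion_kb(three), lex)), 0)
  expect_equal(nrow(mine_patterns(build_opinion_kb(four[0, ]), lex)), 0)
})

test_that("mined patterns match a brute-force reimplementation exactly", {
  fix <- generate_fixtures(sim_config(seed = 23, n_reviews = 60))
  res <- build_opinion_resources(
    fix$reviews, fix$domain_kb, fix$store, fix$lexicon, fix$background
  )
  pats <- tibble::as_tibble(res$patterns) |>
    dplyr::arrange(level, effective_code, affected_code, relation)
  expect_gt(nrow(pats), 0)
  oracle <- brute_patterns(res$kb, fix$lexicon) |>
    dplyr::arrange(level, effective_code, affected_code, relation)
  expect_equal(pats, oracle)
})

test_that("classification backs off kb -> type -> group and never skips ahead", {
  kb <- build_opinion_kb(dplyr::bind_rows(
    tagged_quad("accutane", "pain", "reduce", "positive"),
    tagged_quad("accutane", "insomnia", "reduce", "positive"),
    tagged_quad("accutane", "muscle weakness", "reduce", "positive"),
    tagged_quad("accutane", "skin irritation", "reduce", "positive"),
    tagged_quad("cipro", "insomnia", "cause", "negative")
  ))
  pats <- mine_patterns(kb, lex)
  expect_true(any(pats$level == "type"))
  # step 1: a KB member returns its own polarity
  r1 <- classify_quadruples(quad("cipro", "insomnia", "cause"), kb, pats, lex)
  expect_equal(r1$polarity, "negative")
  expect_equal(r1$step, "kb")
  # step 2: absent from the KB, matches the (phsu, sosy, reduce) type pattern
  r2 <- classify_quadruples(quad("advil", "pain", "reduce"), kb, pats, lex)
  expect_equal(r2$polarity, "positive")
  expect_equal(r2$step, "type")
  # step 3 reached only when the type level misses: "acne" is dsyn (not sosy),
  # same DISO group
  r3 <- classify_quadruples(quad("advil", "acne", "reduce"), kb, pats, lex)
  expect_equal(r3$step, if (any(pats$level == "group")) "group" else "none")
  expect_equal(r3$polarity, "positive")
  # exhaustion: nothing matches at any level
  r4 <- classify_quadruples(quad("advil", "confusion", "worsen"), kb, pats, lex)
  expect_equal(r4$polarity, "untagged")
  expect_equal(r4$step, "none")
  # untypeable entity: untagged with a warning
  expect_warning(
    r5 <- classify_quadruples(quad("advil", "zzz", "reduce"), kb, pats, lex),
    "cannot type"
  )
  expect_equal(r5$polarity, "untagged")
})

test_that("every KB member classifies as itself (self-consistency)", {
  fix <- generate_fixtures(sim_config(seed = 29, n_reviews = 40))
  res <- build_opinion_resources(
    fix$reviews, fix$domain_kb, fix$store, fix$lexicon, fix$background
  )
  members <- tibble::as_tibble(res$kb) |>
    dplyr::rename(kb_polarity = "polarity")
  got <- classify_quadruples(members, res$kb, res$patterns, fix$lexicon)
  expect_true(all(got$step == "kb"))
  expect_equal(got$polarity, members$kb_polarity)
})

test_that("the OpinionKB serializes and reads back unchanged", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  kb <- build_opinion_kb(dplyr::bind_rows(
    tagged_quad("accutane", "dry lip", "cause", "negative"),
    tagged_quad("avita", "acne", "decrease", "positive")
  ))
  write_opinion_kb(kb, f)
  back <- read_opinion_kb(f)
  # the conflict-log attribute is not serialized; compare the entries
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(kb),
    ignore_attr = TRUE
  )
})
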