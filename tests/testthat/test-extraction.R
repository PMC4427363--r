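lex <- example_lexicon()
groups <- c("DISO", "ANAT")

test_that("main verbs are the clause relation; phrases have none", {
  u <- prep_units(
    list(drug = "Accutane", benefits = "Accutane cleared my skin."),
    list(drug = "Accutane", side_effects = "Lips were chapped and nose was dried."),
    list(drug = "Accutane", benefits = "no acne"),
    list(drug = "Yasmin", benefits = "Yasmin is supposed to alleviate PMS symptoms.")
  )
  mv1 <- extract_main_verbs(u$tokens[[match("r1_u1", u$unit_id)]])
  expect_equal(mv1$lemma, "clear")
  expect_false(mv1$passive)
  # first clause of the split passive compound
  r2 <- u[u$review_id == 2, ]
  expect_equal(nrow(r2), 2)
  mv2 <- extract_main_verbs(r2$tokens[[1]])
  expect_equal(mv2$lemma, "chap")
  expect_true(mv2$passive)
  # bare phrase: no relation verb
  r3 <- u[u$review_id == 3, ]
  expect_equal(nrow(extract_main_verbs(r3$tokens[[1]])), 0)
  expect_true(r3$is_phrase)
  # control verb: the embedded infinitive is the relation
  r4 <- u[u$review_id == 4, ]
  expect_equal(extract_main_verbs(r4$tokens[[1]])$lemma, "alleviate")
})

test_that("complete opinions pair an effective subject with affected objects", {
  u <- prep_units(
    list(drug = "Yasmin", benefits = "Yasmin is supposed to alleviate PMS symptoms."),
    list(drug = "Avelox", side_effects = "Avelox caused heart palpitations, confusion, and lasting muscle weakness."),
    list(drug = "Accutane", comments = "I love Accutane.")
  )
  m <- tag_entities(u, lex, affected_groups = groups)
  q <- extract_complete_opinions(u, m)
  expect_equal(
    q[q$review_id == 1, c("effective", "affected", "relation")],
    tibble::tibble(effective = "yasmin", affected = "pms symptom", relation = "alleviate")
  )
  av <- q[q$review_id == 2, ]
  expect_equal(nrow(av), 3)
  expect_true(all(av$effective == "avelox" & av$relation == "cause"))
  expect_setequal(av$affected, c("heart palpitation", "confusion", "muscle weakness"))
  expect_true(all(is.na(q$polarity)))
  # drug-only sentence: no affected entity, no quadruple
  expect_equal(sum(q$review_id == 3), 0)
})

test_that("candidate subjects come from preceding noun phrases plus the drug", {
  u <- prep_units(list(
    drug = "Accutane",
    benefits = "My doctor prescribed me Accutane. Within a month, my skin was almost completely cleared."
  ))
  cands <- propose_subject_candidates(u$unit_id[2], u)
  expect_true(all(c("doctor", "accutane") %in% cands))
  # first unit of a review: drug name only
  expect_equal(propose_subject_candidates(u$unit_id[1], u), "accutane")
})

test_that("candidate probabilities normalize and reproduce the worked selection", {
  store <- triple_store(
    arg0 = c("accutane", "dermatologist"),
    predicate = c("clear", "clear"),
    arg1 = c("skin", "face"),
    count = c(2L, 5L)
  )
  sc <- score_subject_candidates(c("doctor", "accutane"), "clear", "skin", store)
  expect_equal(sum(sc$prob), 1, tolerance = 1e-12)
  expect_equal(sc$prob[sc$candidate == "accutane"], 1)
  expect_equal(sc$prob[sc$candidate == "doctor"], 0)
  sel <- select_best_subject(sc, drug_lemmas = "accutane")
  expect_equal(sel$candidate, "accutane")
  expect_true(sel$accepted)
  # single candidate with positive count: probability 1
  one <- score_subject_candidates("accutane", "clear", "skin", store)
  expect_equal(one$prob, 1)
  # no evidence at all: abstain
  none <- score_subject_candidates(c("doctor", "accutane"), "cure", "skin", store)
  expect_true(all(is.na(none$prob)))
  expect_true(select_best_subject(none, "accutane")$abstained)
  # candidate outside C is a contract error
  expect_error(
    score_subject_candidate("nurse", "clear", "skin", store, c("doctor", "accutane")),
    "not in the candidate set"
  )
  expect_equal(
    score_subject_candidate("accutane", "clear", "skin", store, c("doctor", "accutane")),
    1
  )
})

test_that("non-drug winners are rejected and exact ties break toward the drug", {
  store <- triple_store(
    arg0 = c("doctor", "accutane"), predicate = c("clear", "clear"),
    arg1 = c("skin", "skin"), count = c(4L, 4L)
  )
  sc <- score_subject_candidates(c("doctor", "accutane"), "clear", "skin", store)
  sel <- select_best_subject(sc, "accutane")
  expect_equal(sel$candidate, "accutane") # drug-type tie-break
  expect_true(sel$accepted)
  store2 <- triple_store("doctor", "clear", "skin", 4L)
  sel2 <- select_best_subject(
    score_subject_candidates(c("doctor", "accutane"), "clear", "skin", store2),
    "accutane"
  )
  expect_equal(sel2$candidate, "doctor")
  expect_false(sel2$accepted)
})

make_cand <- function(verb, affected, sem_type = "sosy", n = 1,
                      drug = "Accutane", unit = "r1_u2") {
  tibble::tibble(
    review_id = 1L, unit_id = paste0(unit, "_", verb, "_", seq_len(n)),
    field = "benefits", drug = drug, verb = verb, affected = affected,
    affected_sem_type = sem_type, affected_sem_group = "DISO",
    prior = "undesirable", passive = FALSE,
    n_negations = 0L, quantifier = NA_character_,
    candidates = replicate(n, c("doctor", tolower(drug)), simplify = FALSE)
  )
}

test_that("the filter cascade decides each candidate at exactly one stage, in order", {
  store <- triple_store("accutane", "clear", "skin", 2L)
  complete <- quad("accutane", "acne", "reduce")
  dkb <- domain_kb("Accutane", "headache", "benefit", "sosy")
  cands <- dplyr::bind_rows(
    make_cand("clear", "skin", "bdsu"), # stage 1 evidence
    make_cand("reduce", "acne", "dsyn"), # stage 2: matches the complete quad
    make_cand("ease", "headache"), # stage 3: DomainKB
    make_cand("trigger", "nausea", n = 4), # stage 4: frequent (4 > 3)
    make_cand("worsen", "rash", "fndg", n = 3) # infrequent (3, not > 3)
  )
  disp <- run_filter_cascade(cands, complete, dkb, store,
    drug_lemmas = "accutane"
  )
  expect_equal(disp$stage[disp$verb == "clear"], "triple_store")
  expect_equal(disp$stage[disp$verb == "reduce"], "comp_indi")
  expect_equal(disp$stage[disp$verb == "ease"], "domain_kb")
  expect_true(all(disp$stage[disp$verb == "trigger"] == "frequency"))
  expect_true(all(disp$accepted[disp$verb == "trigger"]))
  expect_true(all(disp$stage[disp$verb == "worsen"] == "rejected"))
  expect_true(all(!disp$accepted[disp$verb == "worsen"]))
  # short-circuit: with triple evidence, later stages are not consulted even
  # when they would also match
  c2 <- make_cand("reduce", "acne", "dsyn")
  store2 <- triple_store("accutane", "reduce", "acne", 1L)
  d2 <- run_filter_cascade(c2, complete, dkb, store2, "accutane")
  expect_equal(d2$stage, "triple_store")
  # stage-1 rejection (non-drug winner) is final: decided at stage 1, not
  # passed on to stages 2-4
  store3 <- triple_store("doctor", "reduce", "acne", 3L)
  d3 <- run_filter_cascade(c2, complete, dkb, store3, "accutane")
  expect_equal(d3$stage, "triple_store")
  expect_false(d3$accepted)
})

test_that("cascade decisions are invariant to candidate order", {
  store <- triple_store("accutane", "clear", "skin", 2L)
  dkb <- domain_kb("Accutane", "headache", "benefit", "sosy")
  cands <- dplyr::bind_rows(
    make_cand("clear", "skin", "bdsu"),
    make_cand("ease", "headache"),
    make_cand("trigger", "nausea", n = 5)
  )
  a <- run_filter_cascade(cands, quad("x", "y", "z")[0, ], dkb, store, "accutane")
  b <- run_filter_cascade(cands[rev(seq_len(nrow(cands))), ],
    quad("x", "y", "z")[0, ], dkb, store, "accutane"
  )
  b <- b[order(match(b$unit_id, a$unit_id)), ]
  expect_equal(a$stage, b$stage)
  expect_equal(a$accepted, b$accepted)
})

test_that("phrase patterns extract descriptors and respect the support bound", {
  dkb <- domain_kb(
    c("Accutane", "Accutane"), c("dry skin", "clearing acne"),
    c("side_effect", "benefit"), c("bdsu", "dsyn")
  )
  u <- prep_units(
    list(drug = "Accutane", side_effects = "Very very dry skin"),
    list(drug = "Accutane", benefits = "Clearing of acne"),
    lexicon = lex
  )
  m <- tag_entities(u, lex, affected_groups = groups)
  res <- extract_phrase_opinions(u, m, dkb, beta = 3)
  q <- res$quadruples
  expect_equal(q$affected[q$review_id == 1], "dry skin")
  expect_equal(q$relation[q$review_id == 1], "cause")
  expect_equal(q$route[q$review_id == 1], "phrase_kb")
  expect_equal(q$affected[q$review_id == 2], "clearing acne")
  # unseen tuple: pooled support 4 accepted, 3 rejected (strict > beta)
  mk <- function(n) {
    rows <- purrr::map(seq_len(n), \(i) list(drug = "Advil", side_effects = "Itchy skin"))
    do.call(prep_units, c(rows, list(lexicon = lex)))
  }
  u4 <- mk(4)
  m4 <- tag_entities(u4, lex, affected_groups = groups)
  r4 <- extract_phrase_opinions(u4, m4, empty_dkb(), beta = 3)
  expect_equal(nrow(r4$quadruples), 4)
  expect_true(all(r4$quadruples$route == "phrase_support"))
  u3 <- mk(3)
  m3 <- tag_entities(u3, lex, affected_groups = groups)
  r3 <- extract_phrase_opinions(u3, m3, empty_dkb(), beta = 3)
  expect_equal(nrow(r3$quadruples), 0)
})

test_that("no emitted quadruple has a non-drug effective entity", {
  fix <- generate_fixtures(sim_config(seed = 31, n_reviews = 30))
  res <- build_opinion_resources(
    fix$reviews, fix$domain_kb, fix$store, fix$lexicon, fix$background
  )
  drug_terms <- fix$lexicon$term[fix$lexicon$sem_type == "phsu"]
  expect_true(all(tolower(res$quadruples$effective) %in% drug_terms))
})
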