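dkb9 <- domain_kb(
  drug = c("Accutane", "Avita", "Cipro", "Accutane"),
  effect_term = c("dry lip", "acne", "insomnia", "skin"),
  effect_kind = c("side_effect", "benefit", "side_effect", "benefit"),
  sem_type = c("sosy", "dsyn", "sosy", "bdsu"),
  relation = c(NA, "decrease", NA, "clear")
)

test_that("DomainKB lookup maps benefits to positive and side effects to negative", {
  q <- dplyr::bind_rows(
    quad("accutane", "dry lip", "cause"),
    quad("avita", "acne", "decrease"),
    quad("avita", "acne", "worsen"), # relation constraint blocks the record
    quad("advil", "nausea", "cause") # absent from the KB
  )
  expect_equal(
    lookup_domainkb_polarity(q, dkb9),
    c("negative", "positive", "unknown", "unknown")
  )
})

test_that("valence shifters follow the negation and quantifier rules", {
  # negation flips a known polarity
  expect_equal(apply_valence_shifters("positive", 1L), "negative")
  # double negation is the identity
  expect_equal(apply_valence_shifters("positive", 2L), "positive")
  expect_equal(apply_valence_shifters("negative", 2L), "negative")
  # "less acne": decrease over an undesirable item is positive
  expect_equal(
    apply_valence_shifters(NA, 0L, "decrease", "undesirable"), "positive"
  )
  expect_equal(
    apply_valence_shifters(NA, 0L, "increase", "undesirable"), "negative"
  )
  expect_equal(
    apply_valence_shifters(NA, 0L, "decrease", "desirable"), "negative"
  )
  # empty shifter context leaves the base unchanged
  expect_equal(apply_valence_shifters("positive", 0L), "positive")
  # bare negated undesirable noun ("no acne") is positive
  expect_equal(apply_valence_shifters(NA, 1L, NA, "undesirable"), "positive")
})

test_that("negated known effects flip against the KB polarity end to end", {
  u <- prep_units(list(drug = "Accutane", benefits = "Accutane did not clear my skin."))
  m <- tag_entities(u, example_lexicon(), affected_groups = c("DISO", "ANAT"))
  q <- extract_complete_opinions(u, m)
  expect_equal(q$n_negations, 1L)
  tagged <- assign_polarities(q, u, dkb9)
  expect_equal(tagged$polarity, "negative")
  expect_equal(tagged$pol_source, "domain_kb")
  expect_equal(tagged$confidence, 1)
})

test_that("and/but links propagate polarity to the untagged side", {
  u <- prep_units(
    list(drug = "Accutane", benefits = "Accutane cleared my skin and the acne went away."),
    list(drug = "Accutane", benefits = "Accutane cleared my skin, but I still have breakouts.")
  )
  m <- tag_entities(u, example_lexicon(), affected_groups = c("DISO", "ANAT"))
  and_units <- u[u$review_id == 1, ]
  quads <- dplyr::bind_rows(
    quad("accutane", "skin", "clear",
      unit_id = and_units$unit_id[1], polarity = "positive"
    ),
    quad("accutane", "acne", "go", unit_id = and_units$unit_id[2])
  ) |>
    dplyr::mutate(pol_source = ifelse(is.na(polarity), NA, "domain_kb"),
      confidence = ifelse(is.na(polarity), NA, 1)
    )
  out <- propagate_conjunction_polarity(quads, and_units)
  expect_equal(out$polarity[2], "positive")
  expect_equal(out$pol_source[2], "conjunction")

  but_units <- u[u$review_id == 2, ]
  quads2 <- dplyr::bind_rows(
    quad("accutane", "skin", "clear",
      unit_id = but_units$unit_id[1], polarity = "positive"
    ),
    quad("accutane", "breakout", "have", unit_id = but_units$unit_id[2])
  ) |>
    dplyr::mutate(pol_source = ifelse(is.na(polarity), NA, "domain_kb"),
      confidence = ifelse(is.na(polarity), NA, 1)
    )
  out2 <- propagate_conjunction_polarity(quads2, but_units)
  expect_equal(out2$polarity[2], "negative")
  # no tagged neighbour: nothing changes
  quads3 <- quads2 |> dplyr::mutate(polarity = NA_character_)
  out3 <- propagate_conjunction_polarity(quads3, but_units)
  expect_true(all(is.na(out3$polarity)))
})

test_that("confidence degrees normalize and the 3-vs-1 example is positive", {
  expect_equal(confidence_degree(3, 4), 0.75)
  expect_equal(confidence_degree(3, 4) + confidence_degree(1, 4), 1)
  expect_equal(confidence_degree(4, 4), 1)
  expect_error(confidence_degree(0, 0), "at least one occurrence")

  # an opinion seen 3 times in benefits and once in side effects is positive
  mk_unit <- function(rid, field, uid) {
    tibble::tibble(
      review_id = rid, drug = "Advil", rating = NA_integer_, unit_id = uid,
      field = field, index_in_review = 1L, text = "x", conj = NA_character_,
      conj_with = NA_character_, is_phrase = FALSE,
      tokens = list(tokenize_text("x")), pron_unresolved = 0L
    )
  }
  units <- dplyr::bind_rows(
    mk_unit(1L, "benefits", "r1_u1"), mk_unit(2L, "benefits", "r2_u1"),
    mk_unit(3L, "benefits", "r3_u1"), mk_unit(4L, "side_effects", "r4_u1")
  )
  quads <- dplyr::bind_rows(
    quad("advil", "pain", "reduce", unit_id = "r1_u1", review_id = 1L),
    quad("advil", "pain", "reduce", unit_id = "r2_u1", review_id = 2L),
    quad("advil", "pain", "reduce", unit_id = "r3_u1", review_id = 3L),
    quad("advil", "pain", "reduce",
      unit_id = "r4_u1", review_id = 4L, field = "side_effects"
    )
  )
  tagged <- assign_polarities(quads, units, empty_dkb())
  expect_true(all(tagged$polarity == "positive"))
  expect_equal(tagged$pol_source[4], "structure")
  expect_equal(tagged$confidence[4], 0.75)
})

test_that("the confidence-degree rule overrides a misplaced field", {
  mk_unit <- function(rid, field) {
    tibble::tibble(
      review_id = rid, drug = "Imitrex", rating = NA_integer_,
      unit_id = paste0("r", rid, "_u1"), field = field, index_in_review = 1L,
      text = "x", conj = NA_character_, conj_with = NA_character_,
      is_phrase = FALSE, tokens = list(tokenize_text("x")),
      pron_unresolved = 0L
    )
  }
  fields <- c("benefits", rep("side_effects", 4)) # CD(negative) = 0.8 over 5
  units <- dplyr::bind_rows(purrr::imap(fields, \(f, i) mk_unit(i, f)))
  quads <- dplyr::bind_rows(purrr::imap(fields, \(f, i) {
    quad("imitrex", "flushing", "cause",
      unit_id = paste0("r", i, "_u1"), review_id = i, field = f
    )
  }))
  tagged <- assign_polarities(quads, units, empty_dkb())
  expect_equal(tagged$polarity[1], "negative") # benefits-field occurrence overridden
  expect_equal(tagged$pol_source[1], "structure")
  expect_equal(tagged$confidence[1], 0.8)
})

test_that("basic rule covers singletons; comment-field polarity follows the rating", {
  mk_unit <- function(field, rating) {
    tibble::tibble(
      review_id = 1L, drug = "Advil", rating = rating, unit_id = "r1_u1",
      field = field, index_in_review = 1L, text = "x", conj = NA_character_,
      conj_with = NA_character_, is_phrase = FALSE,
      tokens = list(tokenize_text("x")), pron_unresolved = 0L
    )
  }
  one <- function(field, rating = NA_integer_) {
    assign_polarities(
      quad("advil", "pain", "reduce", field = field),
      mk_unit(field, rating), empty_dkb()
    )
  }
  expect_equal(one("benefits")$polarity, "positive")
  expect_equal(one("benefits")$pol_source, "basic_rule")
  expect_equal(one("side_effects")$polarity, "negative")
  expect_equal(one("comments", 5L)$polarity, "positive")
  expect_equal(one("comments", 1L)$polarity, "negative")
  expect_true(is.na(one("comments", 3L)$polarity)) # mid rating abstains
})

test_that("DomainKB assignments are never overwritten by later steps", {
  fix <- generate_fixtures(sim_config(seed = 17, n_reviews = 40, field_noise_rate = 0.3))
  res <- build_opinion_resources(
    fix$reviews, fix$domain_kb, fix$store, fix$lexicon, fix$background
  )
  q <- res$quadruples
  kb_pol <- lookup_domainkb_polarity(q, fix$domain_kb)
  bare <- q$relation == "cause" & is.na(q$descriptor) &
    (q$n_negations > 0 | !is.na(q$quantifier))
  kb_tagged <- q[q$pol_source %in% "domain_kb", ]
  expect_true(all(kb_tagged$confidence == 1))
  shifted <- apply_valence_shifters(
    ifelse(kb_pol == "unknown", NA, kb_pol),
    q$n_negations, q$quantifier, q$prior
  )
  idx <- which(q$pol_source %in% "domain_kb")
  expect_equal(q$polarity[idx], shifted[idx])
})
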