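#' Simulation configuration for synthetic drug-review fixtures
#'
#' Defines the study conditions the generator emulates. Defaults reflect the
#' composition reported for real druglib-style review corpora: 73% of
#' opinionated sentences are indirect, about 93% of indirect opinions are
#' incomplete, roughly half of the incomplete ones are bare phrases, and
#' about 53% of missing-subject sentences can be resolved from open-IE triple
#' evidence (the remainder splitting over the CompIndi, DomainKB and
#' frequency filters roughly 12:28:7).
#'
#' @param seed Integer RNG seed; the whole fixture set is a deterministic
#'   function of it.
#' @param n_reviews Number of reviews to generate.
#' @param proportion_indirect Share of opinionated sentence slots carrying an
#'   indirect (vs direct) opinion.
#' @param proportion_incomplete Share of indirect opinions whose effective
#'   entity is missing.
#' @param phrase_rate Share of incomplete opinions realised as bare phrases.
#' @param negation_rate,quantifier_rate Shares of phrase opinions realised as
#'   bare negated / quantified nouns.
#' @param field_noise_rate Probability that a standalone opinion is written
#'   into the wrong benefits/side-effects field (its true polarity is
#'   unchanged).
#' @param triple_support_rate Share of incomplete sentence opinions whose
#'   subject is resolvable from the triple store; the rest are routed to the
#'   CompIndi / DomainKB / frequency filters with `route_weights`.
#' @param route_weights Relative weights of the three non-triple cascade
#'   routes (CompIndi, DomainKB, frequency).
#' @param kb_coverage Probability that a planted (drug, effect) pair gets a
#'   DomainKB record (forced records for routes that require one are added on
#'   top).
#' @param kb_phrase_rate Share of described phrases backed by a DomainKB
#'   descriptor record (the rest rely on pooled support).
#' @param passive_rate Share of incomplete sentence opinions realised as
#'   passives.
#' @param conj_rate Probability that a review carries an and/but compound
#'   sentence.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_reviews = 200L,
                       proportion_indirect = 0.73,
                       proportion_incomplete = 0.93,
                       phrase_rate = 0.5,
                       negation_rate = 0.10,
                       quantifier_rate = 0.10,
                       field_noise_rate = 0,
                       triple_support_rate = 0.5319,
                       route_weights = c(
                         comp_indi = 12.23, domain_kb = 27.67, frequency = 6.91
                       ),
                       kb_coverage = 0.6,
                       kb_phrase_rate = 0.6,
                       passive_rate = 0.3,
                       conj_rate = 0.15) {
  rates <- c(
    proportion_indirect, proportion_incomplete, phrase_rate, negation_rate,
    quantifier_rate, field_noise_rate, triple_support_rate, kb_coverage,
    kb_phrase_rate, passive_rate, conj_rate
  )
  stopifnot(all(rates >= 0 & rates <= 1), n_reviews >= 0, length(route_weights) == 3)
  structure(
    list(
      seed = as.integer(seed), n_reviews = as.integer(n_reviews),
      proportion_indirect = proportion_indirect,
      proportion_incomplete = proportion_incomplete,
      phrase_rate = phrase_rate, negation_rate = negation_rate,
      quantifier_rate = quantifier_rate,
      field_noise_rate = field_noise_rate,
      triple_support_rate = triple_support_rate,
      route_weights = route_weights / sum(route_weights),
      kb_coverage = kb_coverage, kb_phrase_rate = kb_phrase_rate,
      passive_rate = passive_rate, conj_rate = conj_rate
    ),
    class = "sim_config"
  )
}

# --- fixed vocabulary pools -------------------------------------------------

sim_drugs <- function() {
  c(
    "Accutane", "Oracea", "Yasmin", "Avelox", "Cipro",
    "Avita", "Advil", "Imitrex", "Strattera", "Prevacid"
  )
}

# (term, sem_type) pools; all DISO, undesirable
sim_benefit_effects <- function() {
  tibble::tibble(
    term = c("acne", "pain", "headache", "heartburn", "anxiety", "migraine", "depression"),
    sem_type = c("dsyn", "sosy", "sosy", "sosy", "mobd", "dsyn", "mobd")
  )
}

sim_side_effects <- function() {
  tibble::tibble(
    term = c("nausea", "dizziness", "insomnia", "rash", "confusion", "drowsiness"),
    sem_type = c("sosy", "sosy", "sosy", "fndg", "mobd", "sosy")
  )
}

# effects reserved for specific generation routes, never sampled elsewhere
sim_dedicated_effects <- function() {
  tibble::tibble(
    term = c("fatigue", "bloating", "redness", "breakout"),
    sem_type = c("sosy", "sosy", "fndg", "fndg"),
    use = c("freq_benefit", "freq_side", "conj_and", "conj_but")
  )
}

sim_verbs <- function() {
  list(
    triple = list(benefit = c("clear", "reduce", "relieve"),
      side = c("cause", "worsen")),
    comp_indi = list(benefit = "alleviate", side = "induce"),
    domain_kb = list(benefit = "ease", side = "give"),
    frequency = list(benefit = "calm", side = "trigger")
  )
}

verb_past <- function(lemma) {
  irr <- c(go = "went", get = "got", give = "gave")
  if (lemma %in% names(irr)) {
    return(unname(irr[lemma]))
  }
  if (stringr::str_detect(lemma, "e$")) {
    paste0(lemma, "d")
  } else {
    paste0(lemma, "ed")
  }
}

# described-phrase pool: template text, descriptor lemma, affected lemma/type
sim_phrases <- function() {
  tibble::tribble(
    ~kind, ~backing, ~text, ~descriptor, ~affected, ~sem_type,
    "benefit", "kb", "Clearing of acne", "clearing", "acne", "dsyn",
    "benefit", "kb", "Relief of pain", "relief", "pain", "sosy",
    "side", "kb", "Very dry skin", "dry", "skin", "bdsu",
    "side", "kb", "Chapped lips", "chapped", "lip", "bpoc",
    "side", "kb", "Stomach cramps", "stomach", "cramp", "sosy",
    "benefit", "support", "Clear skin", "clear", "skin", "bdsu",
    "benefit", "support", "Smooth skin", "smooth", "skin", "bdsu",
    "side", "support", "Itchy rash", "itchy", "rash", "fndg",
    "side", "support", "Severe swelling", "severe", "swelling", "fndg"
  )
}

#' The semantic lexicon shipped with the synthetic fixtures
#'
#' Covers the drug names, the planted affected entities (Disorders and
#' Anatomy groups), temporal/quantitative concepts that occur in review
#' prose, and the restaurant/product vocabulary of the mixed-topic background
#' opinions, so that SGF-IOF group selection can be exercised end to end.
#'
#' @return A [semantic_lexicon()].
#' @export
sim_lexicon <- function() {
  drugs <- tolower(sim_drugs())
  eff <- dplyr::bind_rows(
    sim_benefit_effects(), sim_side_effects(),
    sim_dedicated_effects()[, c("term", "sem_type")]
  )
  extra_diso <- tibble::tibble(
    term = c("cramp", "swelling", "itching", "irritation", "skin irritation",
      "muscle weakness", "palpitation", "heart palpitation"),
    sem_type = c("sosy", "fndg", "sosy", "sosy", "sosy", "sosy", "fndg", "fndg")
  )
  anat <- tibble::tibble(
    term = c("skin", "lip", "nose", "stomach", "heart"),
    sem_type = c("bdsu", "bpoc", "bpoc", "bpoc", "bpoc")
  )
  conc <- tibble::tibble(
    term = c("day", "night", "week", "month", "year", "course", "amount", "time"),
    sem_type = "tmco"
  )
  qnco <- tibble::tibble(term = c("value", "price"), sem_type = "qnco")
  livb <- tibble::tibble(term = c("doctor", "waiter", "chef"), sem_type = "prof")
  objc <- tibble::tibble(
    term = c("meal", "food", "battery", "screen", "phone", "camera", "product"),
    sem_type = "mnob"
  )
  orga <- tibble::tibble(term = "restaurant", sem_type = "orgt")
  tab <- dplyr::bind_rows(
    tibble::tibble(term = drugs, sem_type = "phsu"),
    eff, extra_diso, anat, conc, qnco, livb, objc, orga
  )
  group_of <- c(
    phsu = "CHEM", dsyn = "DISO", sosy = "DISO", fndg = "DISO", mobd = "DISO",
    bdsu = "ANAT", bpoc = "ANAT", tmco = "CONC", qnco = "CONC",
    prof = "LIVB", mnob = "OBJC", orgt = "ORGA"
  )
  semantic_lexicon(tab$term, tab$sem_type, unname(group_of[tab$sem_type]))
}

# Mixed-topic (restaurant/product) opinion lines: the SGF-IOF background.
# Deliberately heavy in the person, temporal/quantitative and object groups
# so those general groups score low in the drug-review domain subset.
sim_background <- function(n_lines) {
  templates <- c(
    "The waiter brought the meal after a long night.",
    "The chef cooked the food all day at the restaurant.",
    "The waiter forgot the food during the meal that night.",
    "The battery of this phone lasts a full day every time.",
    "The screen of the camera failed within a week.",
    "The chef and the waiter worked every night that week.",
    "Great value for the money at this restaurant every time.",
    "The price at the restaurant doubled within a year.",
    "The waiter recommended the meal of the day.",
    "The product arrived after a month and the packaging was fine."
  )
  templates[1 + (seq_len(n_lines) - 1) %% length(templates)]
}

# --- generator ---------------------------------------------------------------

#' Generate seed-deterministic synthetic review fixtures with ground truth
#'
#' Produces every input the pipeline consumes -- reviews, DomainKB, semantic
#' lexicon, triple store, mixed-topic background opinions -- from sentence
#' templates that cover each extraction route: complete subject-verb-object
#' sentences, active missing-subject sentences, passives, described phrases
#' (ADJ+NOUN, NOUN+NOUN, NOUN-of-NOUN), bare negated and quantified nouns,
#' and and/but compounds. Because generation is template-based, the planted
#' ground truth is exact by construction.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_fixtures`: `reviews`, `lexicon`, `domain_kb`,
#'   `store` (triple store), `background` (character lines), `truth` (planted
#'   quadruples with polarity, completeness and route), `slots` (per-slot
#'   bookkeeping used for rate checks) and `config`.
#' @export
generate_fixtures <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_reviews > 0 &&
    (nrow(sim_benefit_effects()) == 0 || length(sim_drugs()) == 0)) {
    stop("empty vocabulary pools", call. = FALSE)
  }
  withr::with_seed(config$seed, generate_fixtures_impl(config))
}

generate_fixtures_impl <- function(config) {
  verbs <- sim_verbs()
  phrases <- sim_phrases()
  drugs <- sim_drugs()
  reviews <- list()
  truth <- list()
  slots <- list()
  kb_forced <- list()
  kb_random <- list()
  triples <- list()

  add_truth <- function(rid, field, drug, affected, relation, polarity,
                        completeness, route) {
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      review_id = rid, field = field, effective = tolower(drug),
      affected = affected, relation = relation, polarity = polarity,
      completeness = completeness, route = route
    )
  }
  force_kb <- function(drug, term, kind, sem_type) {
    kb_forced[[length(kb_forced) + 1L]] <<- tibble::tibble(
      drug = tolower(drug), effect_term = term, effect_kind = kind,
      sem_type = sem_type
    )
  }
  add_triple <- function(drug, verb, affected, count) {
    triples[[length(triples) + 1L]] <<- tibble::tibble(
      arg0 = tolower(drug), predicate = verb, arg1 = affected,
      count = as.integer(count)
    )
  }

  direct_fillers <- c(
    "This drug is amazing.", "This drug was horrible.",
    "I love this medication.", "I really like this drug."
  )
  neutral_fillers <- c(
    "I took it daily with food.", "My doctor prescribed me this drug.",
    "Take with food.", "If you miss a dose, skip it.",
    "I started the course a month before.", "Works well for me."
  )
  time_phrases <- c("within a week", "after a month", "within two weeks", "after three days")

  for (rid in seq_len(config$n_reviews)) {
    drug <- sample(drugs, 1)
    rating <- sample(1:5, 1)
    ben_pool <- sim_benefit_effects()[sample(nrow(sim_benefit_effects())), ]
    side_pool <- sim_side_effects()[sample(nrow(sim_side_effects())), ]
    take_effect <- function(kind) {
      pool <- if (kind == "benefit") ben_pool else side_pool
      if (nrow(pool) == 0) { # pool exhausted: re-deal
        pool <- if (kind == "benefit") sim_benefit_effects() else sim_side_effects()
        pool <- pool[sample(nrow(pool)), ]
      }
      row <- pool[1, ]
      if (kind == "benefit") ben_pool <<- pool[-1, ] else side_pool <<- pool[-1, ]
      row
    }
    field_units <- list(benefits = character(), side_effects = character(),
      comments = character())
    place <- function(field, text) {
      field_units[[field]] <<- c(field_units[[field]], text)
    }

    make_sentence_opinion <- function(kind, field_actual) {
      route <- if (stats::runif(1) < config$triple_support_rate) {
        "triple_store"
      } else {
        sample(c("comp_indi", "domain_kb", "frequency"), 1,
          prob = config$route_weights
        )
      }
      vset <- switch(route,
        triple_store = verbs$triple[[kind]],
        comp_indi = verbs$comp_indi[[kind]],
        domain_kb = verbs$domain_kb[[kind]],
        frequency = verbs$frequency[[kind]]
      )
      v <- sample(rep(vset, 2), 1)
      eff <- if (route == "frequency") {
        ded <- sim_dedicated_effects()
        ded[ded$use == paste0("freq_", if (kind == "benefit") "benefit" else "side"), ]
      } else {
        take_effect(kind)
      }
      term <- eff$term[1]
      if (route == "triple_store") {
        add_triple(drug, v, term, sample(2:9, 1))
      }
      if (route == "domain_kb") {
        force_kb(drug, term,
          if (kind == "benefit") "benefit" else "side_effect", eff$sem_type[1]
        )
      }
      if (route == "comp_indi") {
        # anchor: a complete opinion with the same (drug, v, e) earlier on
        place(field_actual, paste0(drug, " ", verb_past(v), " my ", term, "."))
        add_truth(rid, field_actual, drug, term, v,
          if (kind == "benefit") "positive" else "negative", "complete",
          "complete"
        )
      }
      passive <- stats::runif(1) < config$passive_rate
      text <- if (passive) {
        paste0("My ", term, " was ", verb_past(v), " ",
          sample(time_phrases, 1), "."
        )
      } else {
        paste0(
          stringr::str_to_sentence(verb_past(v)), " my ", term, " ",
          sample(time_phrases, 1), "."
        )
      }
      place(field_actual, text)
      add_truth(rid, field_actual, drug, term, v,
        if (kind == "benefit") "positive" else "negative", "incomplete", route
      )
    }

    make_phrase_opinion <- function(kind, field_actual) {
      u <- stats::runif(1)
      if (kind == "benefit" && u < config$negation_rate) {
        src <- sample(c("benefit", "side"), 1)
        eff <- take_effect(src)
        # KB record carries the term's natural kind; the polarity of the
        # negated phrase itself comes from the desirability prior
        force_kb(drug, eff$term[1],
          if (src == "benefit") "benefit" else "side_effect", eff$sem_type[1]
        )
        place(field_actual, paste0("No ", eff$term[1], "."))
        add_truth(rid, field_actual, drug, eff$term[1], "cause",
          "positive", "incomplete", "phrase_negation"
        )
        return(invisible())
      }
      if (u < config$negation_rate + config$quantifier_rate) {
        eff <- take_effect(kind)
        force_kb(drug, eff$term[1],
          if (kind == "benefit") "benefit" else "side_effect", eff$sem_type[1]
        )
        word <- if (kind == "benefit") "Less" else "More"
        place(field_actual, paste0(word, " ", eff$term[1], "."))
        add_truth(rid, field_actual, drug, eff$term[1], "cause",
          if (kind == "benefit") "positive" else "negative",
          "incomplete", "phrase_quantifier"
        )
        return(invisible())
      }
      backing <- if (stats::runif(1) < config$kb_phrase_rate) "kb" else "support"
      pool <- phrases[phrases$kind == kind & phrases$backing == backing, ]
      row <- pool[sample(nrow(pool), 1), ]
      if (backing == "kb") {
        force_kb(drug, paste(row$descriptor, row$affected),
          if (kind == "benefit") "benefit" else "side_effect", row$sem_type
        )
      }
      place(field_actual, paste0(row$text, "."))
      add_truth(rid, field_actual, drug, paste(row$descriptor, row$affected),
        "cause", if (kind == "benefit") "positive" else "negative",
        "incomplete", paste0("phrase_", backing)
      )
    }

    make_opinion_slot <- function(kind, field_intended) {
      slots[[length(slots) + 1L]] <<- tibble::tibble(
        review_id = rid, kind = "opinion", form = NA_character_,
        field = field_intended
      )
      if (stats::runif(1) >= config$proportion_indirect) {
        place(field_intended, sample(direct_fillers, 1))
        slots[[length(slots)]]$kind <<- "direct"
        return(invisible())
      }
      slots[[length(slots)]]$kind <<- "indirect"
      field_actual <- field_intended
      if (stats::runif(1) < config$field_noise_rate) {
        field_actual <- if (field_intended == "benefits") "side_effects" else "benefits"
      }
      if (stats::runif(1) >= config$proportion_incomplete) {
        slots[[length(slots)]]$form <<- "complete"
        eff <- take_effect(kind)
        v <- sample(rep(verbs$triple[[kind]], 2), 1)
        tmpl <- sample(3, 1)
        text <- switch(tmpl,
          paste0(drug, " ", verb_past(v), " my ", eff$term[1], "."),
          paste0(drug, " really ", verb_past(v), " the ", eff$term[1], "."),
          paste0("It ", verb_past(v), " my ", eff$term[1], ".")
        )
        if (stats::runif(1) < config$kb_coverage) {
          force_kb(drug, eff$term[1],
            if (kind == "benefit") "benefit" else "side_effect", eff$sem_type[1]
          )
        }
        place(field_actual, text)
        add_truth(rid, field_actual, drug, eff$term[1], v,
          if (kind == "benefit") "positive" else "negative",
          "complete", "complete"
        )
      } else if (stats::runif(1) < config$phrase_rate) {
        slots[[length(slots)]]$form <<- "phrase"
        make_phrase_opinion(kind, field_actual)
      } else {
        slots[[length(slots)]]$form <<- "sentence"
        make_sentence_opinion(kind, field_actual)
      }
    }

    n_ben <- sample(1:3, 1)
    n_side <- sample(1:3, 1)
    for (k in seq_len(n_ben)) make_opinion_slot("benefit", "benefits")
    for (k in seq_len(n_side)) make_opinion_slot("side", "side_effects")

    if (stats::runif(1) < config$conj_rate) {
      conj <- sample(c("and", "but"), 1)
      anchor <- take_effect("benefit")
      v <- sample(verbs$triple$benefit, 1)
      force_kb(drug, anchor$term[1], "benefit", anchor$sem_type[1])
      if (conj == "and") {
        text <- paste0(
          drug, " ", verb_past(v), " my ", anchor$term[1],
          ", and the redness went away."
        )
        add_triple(drug, "go", "redness", 5)
        add_truth(rid, "benefits", drug, "redness", "go", "positive",
          "incomplete", "conj_and"
        )
      } else {
        text <- paste0(
          drug, " ", verb_past(v), " my ", anchor$term[1],
          ", but I still get occasional breakouts."
        )
        add_triple(drug, "get", "breakout", 5)
        add_truth(rid, "benefits", drug, "breakout", "get", "negative",
          "incomplete", "conj_but"
        )
      }
      place("benefits", text)
      add_truth(rid, "benefits", drug, anchor$term[1], v, "positive",
        "complete", "complete"
      )
    }

    if (stats::runif(1) < 0.5) {
      place(sample(c("benefits", "side_effects"), 1), sample(neutral_fillers, 1))
    }
    place("comments", sample(neutral_fillers, 1))

    reviews[[rid]] <- tibble::tibble(
      review_id = rid, drug = drug,
      title = paste(drug, "review"), rating = rating,
      benefits = paste(sample(field_units$benefits), collapse = " "),
      side_effects = paste(sample(field_units$side_effects), collapse = " "),
      comments = paste(field_units$comments, collapse = " ")
    )
  }

  reviews <- if (length(reviews) > 0) dplyr::bind_rows(reviews) else empty_reviews()
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else NULL
  truth <- truth %||% tibble::tibble(
    review_id = integer(), field = character(), effective = character(),
    affected = character(), relation = character(), polarity = character(),
    completeness = character(), route = character()
  )
  # random DomainKB coverage of planted sentence-route effects, plus the
  # records individual routes force; duplicates collapse to one record
  kb_all <- dplyr::bind_rows(kb_forced, build_random_kb(truth, config))
  if (nrow(kb_all) > 0) {
    kb_all <- dplyr::distinct(kb_all, .data$drug, .data$effect_term,
      .data$effect_kind,
      .keep_all = TRUE
    )
  }
  dkb <- if (nrow(kb_all) > 0) {
    domain_kb(kb_all$drug, kb_all$effect_term, kb_all$effect_kind, kb_all$sem_type)
  } else {
    domain_kb(character(), character(), character(), character())
  }
  store_tab <- dplyr::bind_rows(
    triples,
    # inert distractors: predicates never queried by the cascade
    tibble::tibble(
      arg0 = c("doctor", "doctor", "patient"),
      predicate = c("prescribe", "recommend", "take"),
      arg1 = c("accutane", "advil", "cipro"),
      count = c(12L, 7L, 20L)
    )
  )
  store <- triple_store(store_tab$arg0, store_tab$predicate, store_tab$arg1,
    store_tab$count
  )
  structure(
    list(
      reviews = reviews,
      lexicon = sim_lexicon(),
      domain_kb = dkb,
      store = store,
      background = sim_background(6 * config$n_reviews),
      truth = truth,
      slots = if (length(slots) > 0) dplyr::bind_rows(slots) else
        tibble::tibble(
          review_id = integer(), kind = character(), form = character(),
          field = character()
        ),
      config = config
    ),
    class = "sim_fixtures"
  )
}

# random coverage rows for triple-route and conjunction effects (sentence
# routes that do not *require* a KB record but may realistically have one);
# frequency-route effects are kept out so the frequency filter stays reachable
build_random_kb <- function(truth, config) {
  cand <- truth[truth$route %in% c("triple_store"), , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  keep <- stats::runif(nrow(cand)) < config$kb_coverage
  cand <- cand[keep, , drop = FALSE]
  if (nrow(cand) == 0) {
    return(NULL)
  }
  types <- dplyr::bind_rows(
    sim_benefit_effects(), sim_side_effects(), sim_dedicated_effects()
  )
  tibble::tibble(
    drug = cand$effective,
    effect_term = cand$affected,
    effect_kind = ifelse(cand$polarity == "positive", "benefit", "side_effect"),
    sem_type = types$sem_type[match(cand$affected, types$term)]
  )
}

#' Write fixture files in the dialects the pipeline consumes
#'
#' @param fixtures A `sim_fixtures` list.
#' @param dir Output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(fixtures, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    reviews = file.path(dir, "reviews.jsonl"),
    lexicon = file.path(dir, "lexicon.tsv"),
    domain_kb = file.path(dir, "domain_kb.tsv"),
    triples = file.path(dir, "triples.tsv"),
    background = file.path(dir, "background.txt"),
    truth = file.path(dir, "truth.tsv")
  )
  write_reviews(fixtures$reviews, paths[["reviews"]])
  write_semantic_lexicon(fixtures$lexicon, paths[["lexicon"]])
  write_domain_kb(fixtures$domain_kb, paths[["domain_kb"]])
  write_triple_store(fixtures$store, paths[["triples"]])
  readr::write_lines(fixtures$background, paths[["background"]])
  readr::write_tsv(fixtures$truth, paths[["truth"]])
  invisible(paths)
}
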