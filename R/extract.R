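#' Extract the main relation verb of a unit
#'
#' Returns the finite main verb of the clause (auxiliaries and modals are
#' treated as features, not relations). Passive constructions ("Lips were
#' chapped") are recognised and flagged. When the main verb is a
#' raising/control verb followed by a to-infinitive ("is supposed to
#' alleviate"), the embedded verb is the relation. Copular-only units have no
#' relation verb and fall through to phrase handling.
#'
#' @param tokens A token tibble from [tokenize_text()].
#' @return A tibble with zero or one row: `lemma`, `index` (token row),
#'   `passive`.
#' @export
extract_main_verbs <- function(tokens) {
  none <- tibble::tibble(lemma = character(), index = integer(), passive = logical())
  i <- first_main_verb_index(tokens)
  if (is.na(i)) {
    return(none)
  }
  passive <- is_passive_at(tokens, i)
  control <- c("suppose", "seem", "try", "want", "help", "like", "start", "continue")
  if (tokens$lemma[i] %in% control) {
    k <- i + 1
    while (k < nrow(tokens) && tokens$pos[k] %in% c("ADV", "PART")) k <- k + 1
    if (k < nrow(tokens) && tolower(tokens$surface[k]) == "to" &&
      tokens$pos[k + 1] == "VERB" && identical(tokens$vform[k + 1], "base")) {
      return(tibble::tibble(
        lemma = tokens$lemma[k + 1], index = k + 1L, passive = FALSE
      ))
    }
  }
  tibble::tibble(lemma = tokens$lemma[i], index = i, passive = passive)
}

# Shifter context: negations in a window before the verb / descriptor,
# quantifier directly modifying the affected mention.
shifter_context <- function(tokens, verb_index, affected_tok_first,
                            window = 4L) {
  neg <- 0L
  anchor <- if (!is.na(verb_index)) verb_index else affected_tok_first
  if (!is.na(anchor) && anchor > 1) {
    rng <- seq(max(1L, anchor - window), anchor - 1L)
    neg <- sum(tokens$pos[rng] == "PART" &
      tokens$lemma[rng] %in% c("not", "no", "never", "n't", "none"))
  }
  quant <- NA_character_
  if (!is.na(affected_tok_first) && affected_tok_first > 1) {
    lo <- max(1L, affected_tok_first - 2L)
    rng <- seq(lo, affected_tok_first - 1L)
    qi <- which(tokens$pos[rng] == "QUANT")
    if (length(qi) > 0) quant <- tokens$direction[rng[qi[length(qi)]]]
  }
  list(n_negations = neg, quantifier = quant)
}

empty_quadruples <- function() {
  tibble::tibble(
    review_id = integer(), unit_id = character(), field = character(),
    effective = character(), affected = character(), relation = character(),
    polarity = character(), completeness = character(), route = character(),
    affected_sem_type = character(), affected_sem_group = character(),
    prior = character(), descriptor = character(),
    n_negations = integer(), quantifier = character()
  )
}

#' Extract complete indirect opinions
#'
#' A complete opinion has both entities present. The bundled positional rule
#' set locates the subject as the nearest typed mention preceding the main
#' verb and objects as typed mentions following it; if the subject is
#' effective-typed and an object affected-typed (reversed for passives), one
#' polarity-null quadruple is emitted per affected object mention. Typing
#' mismatches yield no quadruple.
#'
#' @param units A preprocessed units tibble.
#' @param mentions Mentions from [tag_entities()] with roles assigned.
#' @return A quadruples tibble (`completeness = "complete"`).
#' @export
extract_complete_opinions <- function(units, mentions) {
  out <- purrr::pmap(
    units[, c("unit_id", "review_id", "field", "tokens")],
    function(unit_id, review_id, field, tokens) {
      m <- mentions[mentions$unit_id == unit_id, , drop = FALSE]
      if (!any(m$role == "effective") || !any(m$role == "affected")) {
        return(NULL)
      }
      mv <- extract_main_verbs(tokens)
      if (nrow(mv) == 0) {
        return(NULL)
      }
      typed <- m[m$role %in% c("effective", "affected"), , drop = FALSE]
      before <- typed[typed$tok_last < mv$index, , drop = FALSE]
      after <- typed[typed$tok_first > mv$index, , drop = FALSE]
      if (nrow(before) == 0 || nrow(after) == 0) {
        return(NULL)
      }
      subj <- before[which.max(before$tok_last), ]
      if (!mv$passive) {
        if (subj$role != "effective") {
          return(NULL)
        }
        objs <- after[after$role == "affected", , drop = FALSE]
        eff <- subj$lemma
      } else {
        # passive with an expressed agent: surface subject is affected,
        # the effective entity follows the verb ("... was caused by Avelox")
        if (subj$role != "affected") {
          return(NULL)
        }
        agents <- after[after$role == "effective", , drop = FALSE]
        if (nrow(agents) == 0) {
          return(NULL)
        }
        eff <- agents$lemma[1]
        objs <- subj
      }
      if (nrow(objs) == 0) {
        return(NULL)
      }
      purrr::pmap(objs, function(lemma, sem_type, sem_group, prior,
                                 tok_first, ...) {
        ctx <- shifter_context(tokens, mv$index, tok_first)
        tibble::tibble(
          review_id = review_id, unit_id = unit_id, field = field,
          effective = eff, affected = lemma, relation = mv$lemma,
          polarity = NA_character_, completeness = "complete",
          route = "complete",
          affected_sem_type = sem_type, affected_sem_group = sem_group,
          prior = prior, descriptor = NA_character_,
          n_negations = ctx$n_negations, quantifier = ctx$quantifier
        )
      }) |> dplyr::bind_rows()
    }
  )
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) empty_quadruples() else res
}

#' Propose candidate subjects for a missing effective entity
#'
#' For the first unit of a review the only candidate is the review's drug
#' name. Otherwise the candidates are the noun-phrase heads of all preceding
#' units of the review (most recent first) plus the drug name, deduplicated.
#'
#' @param unit_id Unit to resolve.
#' @param units The review's units tibble (all units, original order).
#' @param window Number of preceding units to consider (`Inf` = all).
#' @return Character vector of candidate lemmas (lowercase).
#' @export
propose_subject_candidates <- function(unit_id, units, window = Inf) {
  i <- match(unit_id, units$unit_id)
  stopifnot(!is.na(i))
  rid <- units$review_id[i]
  drug <- tolower(units$drug[i])
  prev <- units[units$review_id == rid &
    units$index_in_review < units$index_in_review[i], , drop = FALSE]
  if (is.finite(window) && nrow(prev) > window) {
    prev <- prev[seq(nrow(prev) - window + 1, nrow(prev)), , drop = FALSE]
  }
  if (nrow(prev) == 0) {
    return(drug)
  }
  heads <- purrr::map(rev(seq_len(nrow(prev))), function(j) {
    tk <- prev$tokens[[j]]
    idx <- which(tk$pos == "NOUN")
    # NP head: a noun not immediately followed by another noun
    idx <- idx[!(idx + 1) %in% which(tk$pos == "NOUN")]
    rev(tolower(tk$lemma[idx]))
  })
  cands <- unique(c(unlist(heads), drug))
  cands
}

#' Score one subject candidate against the triple store
#'
#' The probability of candidate `c` filling the subject slot of relation
#' `(v, e)` is its triple count divided by the summed counts over the whole
#' candidate set. When no candidate has any triple (denominator 0) the
#' operation abstains, signalling "no open-IE evidence" to the filter cascade.
#'
#' @param c Candidate lemma; must be a member of `candidates`.
#' @param v Verb lemma.
#' @param e Affected-entity lemma.
#' @param store A [triple_store()].
#' @param candidates The full candidate set `C`.
#' @return A probability in `[0, 1]`, or `NA` when the store abstains.
#' @export
score_subject_candidate <- function(c, v, e, store, candidates) {
  if (!tolower(c) %in% tolower(candidates)) {
    stop("candidate '", c, "' is not in the candidate set", call. = FALSE)
  }
  tab <- score_subject_candidates(candidates, v, e, store)
  tab$prob[match(tolower(c), tab$candidate)]
}

#' @rdname score_subject_candidate
#' @return For [score_subject_candidates()]: a tibble `candidate`, `count`,
#'   `prob` (all `prob` `NA` on abstention), candidates in the given order.
#' @export
score_subject_candidates <- function(candidates, v, e, store) {
  counts <- triple_count(store, candidates, v, e)
  denom <- sum(counts)
  tibble::tibble(
    candidate = tolower(candidates),
    count = counts,
    prob = if (denom == 0) NA_real_ else counts / denom
  )
}

#' Select the best subject candidate
#'
#' Argmax over candidate probabilities; ties are broken in favour of
#' drug-typed candidates, then by recency (the candidate order). The sentence
#' is accepted as an incomplete indirect opinion only when the winner is
#' drug-typed.
#'
#' @param scores Tibble from [score_subject_candidates()], in recency order.
#' @param drug_lemmas Lowercase lemmas counted as drug-typed.
#' @return List with `candidate`, `accepted`, `abstained`.
#' @export
select_best_subject <- function(scores, drug_lemmas) {
  if (nrow(scores) == 0 || all(is.na(scores$prob))) {
    return(list(candidate = NA_character_, accepted = NA, abstained = TRUE))
  }
  drug_lemmas <- tolower(drug_lemmas)
  best <- max(scores$prob, na.rm = TRUE)
  at <- which(scores$prob == best)
  if (length(at) > 1) {
    drugged <- at[scores$candidate[at] %in% drug_lemmas]
    at <- if (length(drugged) > 0) drugged[1] else at[1]
  } else {
    at <- at[1]
  }
  winner <- scores$candidate[at]
  list(
    candidate = winner,
    accepted = winner %in% drug_lemmas,
    abstained = FALSE
  )
}

#' Collect candidate incomplete opinions
#'
#' A candidate is created for every unit with at least one affected mention,
#' no effective mention and a main verb (active missing-subject sentences and
#' passives), one per affected mention.
#'
#' @param units Preprocessed units.
#' @param mentions Mentions with roles.
#' @param window Candidate window passed to [propose_subject_candidates()].
#' @return Candidate tibble with a `candidates` list-column.
#' @export
propose_incomplete_candidates <- function(units, mentions, window = Inf) {
  rows <- purrr::pmap(
    units[, c("unit_id", "review_id", "drug", "field", "tokens")],
    function(unit_id, review_id, drug, field, tokens) {
      m <- mentions[mentions$unit_id == unit_id, , drop = FALSE]
      if (any(m$role == "effective") || !any(m$role == "affected")) {
        return(NULL)
      }
      mv <- extract_main_verbs(tokens)
      if (nrow(mv) == 0) {
        return(NULL)
      }
      aff <- m[m$role == "affected", , drop = FALSE]
      purrr::pmap(aff, function(lemma, sem_type, sem_group, prior,
                                tok_first, ...) {
        ctx <- shifter_context(tokens, mv$index, tok_first)
        tibble::tibble(
          review_id = review_id, unit_id = unit_id, field = field,
          drug = drug, verb = mv$lemma, affected = lemma,
          affected_sem_type = sem_type, affected_sem_group = sem_group,
          prior = prior, passive = mv$passive,
          n_negations = ctx$n_negations, quantifier = ctx$quantifier
        )
      }) |> dplyr::bind_rows()
    }
  )
  cands <- dplyr::bind_rows(rows)
  if (nrow(cands) == 0) {
    return(cands)
  }
  cands$candidates <- purrr::map(
    cands$unit_id, propose_subject_candidates,
    units = units, window = window
  )
  cands
}

#' Run the four-stage filter cascade over incomplete-opinion candidates
#'
#' Stages run strictly in order and each later stage is consulted only when
#' all earlier ones abstained:
#' 1. **triple store** — subject resolution by candidate probabilities;
#'    accept/reject by whether the winning candidate is drug-typed; abstains
#'    when no candidate has open-IE evidence.
#' 2. **CompIndi** — accept when `(drug, v, e)` occurs among the previously
#'    extracted complete quadruples (drug-specific unless `any_drug`).
#' 3. **DomainKB** — accept when `(v, e)` matches a DomainKB record for the
#'    drug (a record with no relation verb matches any verb).
#' 4. **frequency** — accept when the tuple `(v, affected-entity-semantic-
#'    type)` occurs strictly more than `freq_threshold` times across all
#'    candidates; otherwise reject.
#'
#' The frequency pool is computed over the full candidate batch before stage 4
#' runs, so decisions do not depend on candidate processing order.
#'
#' @param candidates Candidate tibble from [propose_incomplete_candidates()].
#' @param complete_quads Quadruples from [extract_complete_opinions()].
#' @param dkb A [domain_kb()].
#' @param store A [triple_store()].
#' @param drug_lemmas Lowercase lemmas counted as drug-typed.
#' @param freq_threshold Strict lower bound for stage 4 (default 3).
#' @param any_drug Match CompIndi across drugs instead of drug-specific.
#' @return The candidate tibble extended with `stage`, `accepted`,
#'   `resolved_subject`.
#' @export
run_filter_cascade <- function(candidates, complete_quads, dkb, store,
                               drug_lemmas, freq_threshold = 3,
                               any_drug = FALSE) {
  n <- nrow(candidates)
  if (n == 0) {
    candidates$stage <- character()
    candidates$accepted <- logical()
    candidates$resolved_subject <- character()
    return(candidates)
  }
  pool <- candidates |>
    dplyr::count(.data$verb, .data$affected_sem_type, name = "pool_n")
  stage <- character(n)
  accepted <- logical(n)
  resolved <- rep(NA_character_, n)
  comp_keys <- if (nrow(complete_quads) > 0) {
    paste(
      tolower(complete_quads$effective), tolower(complete_quads$relation),
      tolower(complete_quads$affected)
    )
  } else {
    character()
  }
  comp_keys_any <- if (nrow(complete_quads) > 0) {
    paste(tolower(complete_quads$relation), tolower(complete_quads$affected))
  } else {
    character()
  }
  for (i in seq_len(n)) {
    drug <- tolower(candidates$drug[i])
    v <- tolower(candidates$verb[i])
    e <- tolower(candidates$affected[i])
    # stage 1: triple-store subject resolution
    sc <- score_subject_candidates(candidates$candidates[[i]], v, e, store)
    sel <- select_best_subject(sc, c(drug_lemmas, drug))
    if (!sel$abstained) {
      stage[i] <- "triple_store"
      accepted[i] <- sel$accepted
      resolved[i] <- if (sel$accepted) sel$candidate else NA_character_
      next
    }
    # stage 2: CompIndi
    hit2 <- if (any_drug) {
      paste(v, e) %in% comp_keys_any
    } else {
      paste(drug, v, e) %in% comp_keys
    }
    if (hit2) {
      stage[i] <- "comp_indi"
      accepted[i] <- TRUE
      resolved[i] <- drug
      next
    }
    # stage 3: DomainKB
    hit3 <- any(dkb$drug == drug & dkb$effect_term == e &
      (is.na(dkb$relation) | dkb$relation == v))
    if (hit3) {
      stage[i] <- "domain_kb"
      accepted[i] <- TRUE
      resolved[i] <- drug
      next
    }
    # stage 4: frequency over the full batch
    pn <- pool$pool_n[pool$verb == candidates$verb[i] &
      pool$affected_sem_type == candidates$affected_sem_type[i]]
    if (length(pn) == 1 && pn > freq_threshold) {
      stage[i] <- "frequency"
      accepted[i] <- TRUE
      resolved[i] <- drug
    } else {
      stage[i] <- "rejected"
      accepted[i] <- FALSE
    }
  }
  candidates$stage <- stage
  candidates$accepted <- accepted
  candidates$resolved_subject <- resolved
  candidates
}

cascade_to_quadruples <- function(dispositions) {
  acc <- dispositions[dispositions$accepted, , drop = FALSE]
  if (nrow(acc) == 0) {
    return(empty_quadruples())
  }
  tibble::tibble(
    review_id = acc$review_id, unit_id = acc$unit_id, field = acc$field,
    effective = tolower(acc$drug), affected = acc$affected,
    relation = acc$verb, polarity = NA_character_,
    completeness = "incomplete", route = acc$stage,
    affected_sem_type = acc$affected_sem_type,
    affected_sem_group = acc$affected_sem_group,
    prior = acc$prior, descriptor = NA_character_,
    n_negations = acc$n_negations, quantifier = acc$quantifier
  )
}

#' Extract incomplete opinions from bare phrases
#'
#' Phrases (units without a finite verb) describe effects through linguistic
#' patterns: ADJ+NOUN ("dry skin"), NOUN+NOUN ("stomach cramps"),
#' NOUN-of-NOUN ("clearing of acne"), plus bare negated or quantified nouns
#' ("no acne", "less acne") whose shifters are handed to the polarity module.
#' A descriptor tuple `(descriptor, affected-semantic-type)` found in the
#' DomainKB is accepted immediately; otherwise it joins a second candidate
#' list and is accepted only when its pooled support across all phrase units
#' strictly exceeds `beta`. Bare shifter phrases carry no descriptor to pool,
#' so they are accepted only on a DomainKB term match. Accepted phrases
#' become quadruples `(drug, descriptor affected, cause, null)`.
#'
#' @param units Preprocessed units (phrase units are selected internally).
#' @param mentions Mentions with roles.
#' @param dkb A [domain_kb()].
#' @param beta Minimum-support bound (strict; default 3).
#' @param accept_all Skip the filtering (test-time classification mode):
#'   every phrase candidate is accepted.
#' @return List: `quadruples`, `dispositions` (one row per phrase candidate).
#' @export
extract_phrase_opinions <- function(units, mentions, dkb, beta = 3,
                                    accept_all = FALSE) {
  ph <- units[units$is_phrase, , drop = FALSE]
  rows <- purrr::pmap(
    ph[, c("unit_id", "review_id", "drug", "field", "tokens")],
    function(unit_id, review_id, drug, field, tokens) {
      m <- mentions[mentions$unit_id == unit_id & mentions$role == "affected", ,
        drop = FALSE
      ]
      if (nrow(m) == 0) {
        return(NULL)
      }
      purrr::pmap(m, function(lemma, sem_type, sem_group, prior, tok_first,
                              tok_last, ...) {
        d <- phrase_descriptor(tokens, tok_first, tok_last)
        ctx <- shifter_context(tokens, NA_integer_, tok_first)
        tibble::tibble(
          review_id = review_id, unit_id = unit_id, field = field,
          drug = drug, affected = lemma, affected_sem_type = sem_type,
          affected_sem_group = sem_group, prior = prior,
          descriptor = d, n_negations = ctx$n_negations,
          quantifier = ctx$quantifier
        )
      }) |> dplyr::bind_rows()
    }
  )
  cands <- dplyr::bind_rows(rows)
  if (nrow(cands) == 0) {
    return(list(quadruples = empty_quadruples(), dispositions = cands))
  }
  # pooled support of descriptor tuples over all phrase candidates
  pool <- cands |>
    dplyr::filter(!is.na(.data$descriptor)) |>
    dplyr::count(.data$descriptor, .data$affected_sem_type, name = "support")
  kb_desc <- dkb |>
    tibble::as_tibble() |>
    dplyr::mutate(
      kb_descriptor = ifelse(
        stringr::str_detect(.data$effect_term, "\\s"),
        stringr::str_extract(.data$effect_term, "^\\S+"),
        NA_character_
      )
    )
  disp <- cands |>
    dplyr::mutate(
      kb_hit = purrr::pmap_lgl(
        list(.data$descriptor, .data$affected, .data$affected_sem_type),
        function(d, a, ty) {
          if (!is.na(d)) {
            any(!is.na(kb_desc$kb_descriptor) & kb_desc$kb_descriptor == d &
              kb_desc$sem_type == ty)
          } else {
            any(kb_desc$effect_term == a)
          }
        }
      ),
      support = dplyr::left_join(
        dplyr::pick("descriptor", "affected_sem_type"), pool,
        by = c("descriptor", "affected_sem_type")
      )$support,
      support = dplyr::coalesce(.data$support, 0L),
      stage = dplyr::case_when(
        accept_all ~ "unfiltered",
        .data$kb_hit ~ "phrase_kb",
        !is.na(.data$descriptor) & .data$support > beta ~ "phrase_support",
        TRUE ~ "rejected"
      ),
      accepted = .data$stage != "rejected"
    )
  acc <- disp[disp$accepted, , drop = FALSE]
  quads <- if (nrow(acc) == 0) {
    empty_quadruples()
  } else {
    tibble::tibble(
      review_id = acc$review_id, unit_id = acc$unit_id, field = acc$field,
      effective = tolower(acc$drug),
      affected = ifelse(is.na(acc$descriptor), acc$affected,
        paste(acc$descriptor, acc$affected)
      ),
      relation = "cause", polarity = NA_character_,
      completeness = "incomplete", route = acc$stage,
      affected_sem_type = acc$affected_sem_type,
      affected_sem_group = acc$affected_sem_group,
      prior = acc$prior, descriptor = acc$descriptor,
      n_negations = acc$n_negations, quantifier = acc$quantifier
    )
  }
  list(quadruples = quads, dispositions = disp)
}

# descriptor of an affected mention inside a phrase:
# ADJ+NOUN, NOUN+NOUN, or NOUN-of-NOUN; NA when none applies.
phrase_descriptor <- function(tokens, tok_first, tok_last) {
  if (tok_first > 1) {
    prev <- tok_first - 1L
    if (tokens$pos[prev] == "ADJ") {
      return(tokens$lemma[prev])
    }
    if (tokens$pos[prev] == "NOUN") {
      return(tokens$lemma[prev])
    }
  }
  # NOUN-of-NOUN: "<descriptor> of <mention>"
  if (tok_first > 2 &&
    tolower(tokens$surface[tok_first - 1L]) == "of" &&
    tokens$pos[tok_first - 2L] == "NOUN") {
    return(tokens$lemma[tok_first - 2L])
  }
  # allow a determiner between "of" and the mention
  if (tok_first > 3 &&
    tokens$pos[tok_first - 1L] == "DET" &&
    tolower(tokens$surface[tok_first - 2L]) == "of" &&
    tokens$pos[tok_first - 3L] == "NOUN") {
    return(tokens$lemma[tok_first - 3L])
  }
  NA_character_
}

#' Extract all indirect opinions from preprocessed units
#'
#' Orchestrates complete-opinion extraction, the incomplete-sentence filter
#' cascade and phrase handling. The per-candidate dispositions of the cascade
#' and the phrase route are attached as the `"log"` attribute.
#'
#' @param units Preprocessed units ([prep_reviews()]).
#' @param mentions Mentions with roles ([tag_entities()]).
#' @param dkb A [domain_kb()].
#' @param store A [triple_store()].
#' @param lexicon The [semantic_lexicon()] (supplies drug-typed lemmas).
#' @param beta,freq_threshold,any_drug,window See [run_filter_cascade()] and
#'   [extract_phrase_opinions()].
#' @return A quadruples tibble with polarity `NA`, attribute `log`.
#' @export
extract_opinions <- function(units, mentions, dkb, store, lexicon,
                             beta = 3, freq_threshold = 3, any_drug = FALSE,
                             window = Inf) {
  drug_lemmas <- lexicon$term[lexicon$sem_type %in% attr(lexicon, "drug_types")]
  complete <- extract_complete_opinions(units, mentions)
  cands <- propose_incomplete_candidates(units, mentions, window = window)
  disp <- run_filter_cascade(cands, complete, dkb, store, drug_lemmas,
    freq_threshold = freq_threshold, any_drug = any_drug
  )
  incomplete <- cascade_to_quadruples(disp)
  phr <- extract_phrase_opinions(units, mentions, dkb, beta = beta)
  quads <- dplyr::bind_rows(complete, incomplete, phr$quadruples)
  # effective entities must be drug-typed
  ok <- tolower(quads$effective) %in%
    c(drug_lemmas, tolower(unique(units$drug)))
  quads <- quads[ok, , drop = FALSE]
  attr(quads, "log") <- list(cascade = disp, phrases = phr$dispositions)
  quads
}
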