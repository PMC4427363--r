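#' DomainKB polarity lookup
#'
#' An opinion that expresses a known effect of the drug is positive, a known
#' side effect negative. Matching is on `(drug, affected term)` with the
#' relation verb as an optional extra constraint: a DomainKB record with no
#' relation matches any verb, a record with a relation must agree with the
#' quadruple's relation.
#'
#' @param quads A quadruples tibble (polarity-null).
#' @param dkb A [domain_kb()].
#' @return Character vector, one of `positive` / `negative` / `unknown` per
#'   quadruple.
#' @export
lookup_domainkb_polarity <- function(quads, dkb) {
  if (nrow(quads) == 0) {
    return(character())
  }
  purrr::pmap_chr(
    quads[, c("effective", "affected", "relation")],
    function(effective, affected, relation) {
      hits <- dkb[dkb$drug == tolower(effective) &
        dkb$effect_term == tolower(affected) &
        (is.na(dkb$relation) | dkb$relation == tolower(relation)), ,
      drop = FALSE
      ]
      if (nrow(hits) == 0) {
        return("unknown")
      }
      if (hits$effect_kind[1] == "benefit") "positive" else "negative"
    }
  )
}

#' Apply valence shifters to a base polarity
#'
#' Quantifier rule first: a decrease quantifier over an undesirable affected
#' entity yields positive ("less acne"), over a desirable one negative;
#' mirrored for increase quantifiers. When no base polarity is known, the
#' desirability prior supplies it (undesirable entity mentioned on its own is
#' a negative fact). Then each in-scope negation flips the current polarity,
#' so an even negation count is the identity.
#'
#' @param base Character: `positive` / `negative` / `NA` (unknown).
#' @param n_negations Integer count of in-scope negations.
#' @param quantifier `decrease`, `increase` or `NA`.
#' @param prior Desirability prior of the affected entity
#'   (`desirable` / `undesirable` / `neutral`).
#' @return Character vector of polarities (`NA` where nothing applies).
#' @export
apply_valence_shifters <- function(base, n_negations = 0L,
                                   quantifier = NA_character_,
                                   prior = "neutral") {
  n <- max(length(base), length(n_negations), length(quantifier), length(prior))
  base <- rep_len(base, n)
  n_negations <- rep_len(n_negations, n)
  quantifier <- rep_len(quantifier, n)
  prior <- rep_len(prior, n)
  flip <- function(p) ifelse(p == "positive", "negative", "positive")
  out <- base
  # quantifier direction combined with item orientation
  q_pol <- dplyr::case_when(
    quantifier == "decrease" & prior == "undesirable" ~ "positive",
    quantifier == "decrease" & prior == "desirable" ~ "negative",
    quantifier == "increase" & prior == "undesirable" ~ "negative",
    quantifier == "increase" & prior == "desirable" ~ "positive",
    TRUE ~ NA_character_
  )
  out <- ifelse(!is.na(q_pol), q_pol, out)
  # no base and no quantifier: the prior itself sets the base
  prior_pol <- dplyr::case_when(
    prior == "undesirable" ~ "negative",
    prior == "desirable" ~ "positive",
    TRUE ~ NA_character_
  )
  out <- ifelse(is.na(out), prior_pol, out)
  odd <- !is.na(out) & (n_negations %% 2 == 1)
  out[odd] <- flip(out[odd])
  out
}

#' Confidence degree of a polarity
#'
#' `CD(o, p) = C_p / C`: the fraction of an opinion's occurrences carrying
#' polarity `p` over its total occurrence count `C` (which must be at least
#' 1).
#'
#' @param c_p Occurrences of the opinion with polarity `p`.
#' @param c_total Total occurrences of the opinion.
#' @return Numeric in `[0, 1]`.
#' @export
confidence_degree <- function(c_p, c_total) {
  if (any(c_total < 1)) {
    stop("confidence degree requires at least one occurrence", call. = FALSE)
  }
  if (any(c_p < 0) || any(c_p > c_total)) {
    stop("c_p must lie in [0, c_total]", call. = FALSE)
  }
  c_p / c_total
}

#' Propagate polarity across and/but links
#'
#' "and"-linked clauses usually share a polarity; "but"-linked clauses usually
#' oppose. For every linked pair with exactly one tagged side, the untagged
#' side inherits the same ("and") or the opposite ("but") polarity, applied
#' transitively until a fixpoint. Pairs already tagged inconsistently with
#' their link are left untouched and reported in the `"conflicts"` attribute.
#'
#' @param quads Quadruples with (possibly partial) `polarity`, `pol_source`,
#'   `confidence` columns.
#' @param units Units tibble carrying `conj` / `conj_with` links.
#' @return `quads` with propagated polarities (`pol_source = "conjunction"`).
#' @export
propagate_conjunction_polarity <- function(quads, units) {
  links <- units[!is.na(units$conj), c("unit_id", "conj", "conj_with")]
  conflicts <- list()
  if (nrow(links) == 0 || nrow(quads) == 0) {
    attr(quads, "conflicts") <- dplyr::bind_rows(conflicts)
    return(quads)
  }
  unit_pol <- function(uid) {
    p <- unique(stats::na.omit(quads$polarity[quads$unit_id == uid]))
    if (length(p) == 1) p else NA_character_
  }
  unit_conf <- function(uid) {
    cf <- quads$confidence[quads$unit_id == uid & !is.na(quads$polarity)]
    if (length(cf) > 0) max(cf) else NA_real_
  }
  repeat {
    changed <- FALSE
    for (j in seq_len(nrow(links))) {
      a <- links$conj_with[j]
      b <- links$unit_id[j]
      pa <- unit_pol(a)
      pb <- unit_pol(b)
      same <- links$conj[j] == "and"
      if (!is.na(pa) && !is.na(pb)) {
        consistent <- if (same) pa == pb else pa != pb
        if (!consistent) {
          conflicts[[length(conflicts) + 1L]] <- tibble::tibble(
            unit_a = a, unit_b = b, conj = links$conj[j],
            polarity_a = pa, polarity_b = pb
          )
        }
        next
      }
      if (is.na(pa) && is.na(pb)) next
      src <- if (is.na(pb)) a else b
      dst <- if (is.na(pb)) b else a
      p_src <- if (is.na(pb)) pa else pb
      p_new <- if (same) p_src else if (p_src == "positive") "negative" else "positive"
      rows <- which(quads$unit_id == dst & is.na(quads$polarity))
      if (length(rows) > 0) {
        quads$polarity[rows] <- p_new
        quads$pol_source[rows] <- "conjunction"
        quads$confidence[rows] <- unit_conf(src)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  attr(quads, "conflicts") <- dplyr::bind_rows(conflicts)
  quads
}

field_vote <- function(field, rating, rating_pos = 4, rating_neg = 2) {
  dplyr::case_when(
    field == "benefits" ~ "positive",
    field == "side_effects" ~ "negative",
    field == "comments" & !is.na(rating) & rating >= rating_pos ~ "positive",
    field == "comments" & !is.na(rating) & rating <= rating_neg ~ "negative",
    TRUE ~ NA_character_
  )
}

#' Assign polarity to extracted quadruples
#'
#' Pipeline order:
#' 1. DomainKB lookup plus valence shifters (`source = "domain_kb"`,
#'    confidence 1); bare shifter phrases unknown to the KB get their polarity
#'    from the lexicon desirability prior plus the shifters
#'    (`source = "prior"`).
#' 2. and/but conjunction propagation (`source = "conjunction"`).
#' 3. Review structure: every occurrence of an opinion votes by its field
#'    (benefits positive, side effects negative; comment-field occurrences
#'    vote by the review's overall rating, `>= rating_pos` positive,
#'    `<= rating_neg` negative, otherwise no vote). Opinions with at least
#'    `cd_min` voting occurrences take the argmax confidence-degree polarity
#'    (`source = "structure"`, confidence = CD); the rest fall back to the
#'    basic rule, their own occurrence's vote (`source = "basic_rule"`).
#'
#' Earlier stages are never overwritten by later ones. Comment-field
#' quadruples in reviews rated `rating_neg < rating < rating_pos` with no
#' other evidence stay untagged (`NA`).
#'
#' @param quads Quadruples from [extract_opinions()].
#' @param units Units tibble (conjunction links and ratings).
#' @param dkb A [domain_kb()].
#' @param cd_min Minimum occurrences for the confidence-degree rule.
#' @param rating_pos,rating_neg Rating cutoffs for comment-field votes.
#' @return Quadruples with `polarity`, `pol_source`, `confidence`.
#' @export
assign_polarities <- function(quads, units, dkb, cd_min = 3,
                              rating_pos = 4, rating_neg = 2) {
  if (nrow(quads) == 0) {
    quads$pol_source <- character()
    quads$confidence <- numeric()
    return(quads)
  }
  quads$pol_source <- NA_character_
  quads$confidence <- NA_real_

  # -- step 1: domain knowledge + valence shifters -------------------------
  kb_pol <- lookup_domainkb_polarity(quads, dkb)
  # bare negated/quantified phrases ("no acne", "less acne"): the shifter
  # scopes over the entity itself, not over a drug-effect relation, so the
  # desirability prior supplies the base instead of the DomainKB kind
  bare <- quads$relation == "cause" & is.na(quads$descriptor) &
    (quads$n_negations > 0 | !is.na(quads$quantifier))
  kb_pol[bare] <- "unknown"
  base <- ifelse(kb_pol == "unknown", NA_character_, kb_pol)
  shifted <- apply_valence_shifters(
    base, quads$n_negations, quads$quantifier, quads$prior
  )
  kb_rows <- kb_pol != "unknown"
  quads$polarity[kb_rows] <- shifted[kb_rows]
  quads$pol_source[kb_rows] <- "domain_kb"
  quads$confidence[kb_rows] <- 1
  # prior-based polarity only where a shifter licenses reading the bare term
  prior_rows <- !kb_rows & !is.na(shifted) &
    (quads$n_negations > 0 | !is.na(quads$quantifier))
  quads$polarity[prior_rows] <- shifted[prior_rows]
  quads$pol_source[prior_rows] <- "prior"
  quads$confidence[prior_rows] <- 1

  # -- step 2: and/but propagation -----------------------------------------
  quads <- propagate_conjunction_polarity(quads, units)
  conflicts <- attr(quads, "conflicts")

  # -- step 3: review structure with confidence degrees --------------------
  rating <- units$rating[match(quads$unit_id, units$unit_id)]
  vote <- field_vote(quads$field, rating, rating_pos, rating_neg)
  key <- tolower(paste(quads$effective, quads$affected, quads$relation, sep = "\r"))
  votes_by_key <- tibble::tibble(key = key, vote = vote) |>
    dplyr::filter(!is.na(.data$vote)) |>
    dplyr::summarise(
      c_total = dplyr::n(),
      c_pos = sum(.data$vote == "positive"),
      .by = "key"
    )
  idx <- match(key, votes_by_key$key)
  c_total <- votes_by_key$c_total[idx]
  c_pos <- votes_by_key$c_pos[idx]
  untagged <- is.na(quads$polarity)
  use_cd <- untagged & !is.na(c_total) & c_total >= cd_min &
    (c_pos * 2 != c_total)
  cd_pol <- ifelse(c_pos * 2 > c_total, "positive", "negative")
  quads$polarity[use_cd] <- cd_pol[use_cd]
  quads$pol_source[use_cd] <- "structure"
  quads$confidence[use_cd] <- pmax(c_pos, c_total - c_pos)[use_cd] /
    c_total[use_cd]
  # basic rule for the rest
  basic <- is.na(quads$polarity) & !is.na(vote)
  quads$polarity[basic] <- vote[basic]
  quads$pol_source[basic] <- "basic_rule"
  cd_own <- ifelse(vote == "positive", c_pos, c_total - c_pos) / c_total
  quads$confidence[basic] <- dplyr::coalesce(cd_own[basic], 1)
  attr(quads, "conflicts") <- conflicts
  quads
}
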