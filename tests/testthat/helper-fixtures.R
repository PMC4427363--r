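# Shared fixtures: a small lexicon covering the worked examples, plus
# hand-built stores. Everything is constructed in code.

example_lexicon <- function() {
  semantic_lexicon(
    term = c(
      # drugs
      "accutane", "oracea", "yasmin", "avelox", "cipro", "avita", "advil",
      # disorders
      "acne", "cystic acne", "pain", "pms symptom", "palpitation",
      "heart palpitation", "confusion", "muscle weakness", "skin irritation",
      "insomnia", "redness", "breakout", "bleeding", "dry lip",
      "yeast-infection",
      # anatomy
      "skin", "lip", "nose", "heart",
      # general concepts (Concepts & Ideas)
      "course", "night", "three",
      # people
      "doctor"
    ),
    sem_type = c(
      rep("phsu", 7),
      "dsyn", "dsyn", "sosy", "sosy", "fndg",
      "fndg", "mobd", "sosy", "sosy",
      "sosy", "fndg", "fndg", "patf", "sosy",
      "dsyn",
      "bdsu", "bpoc", "bpoc", "bpoc",
      "tmco", "tmco", "qnco",
      "prof"
    ),
    sem_group = c(
      rep("CHEM", 7),
      rep("DISO", 15),
      rep("ANAT", 4),
      rep("CONC", 3),
      "LIVB"
    )
  )
}

# units tibble from raw review rows, fully preprocessed
prep_units <- function(..., lexicon = example_lexicon()) {
  reviews <- tibble::as_tibble(dplyr::bind_rows(...))
  if (!"review_id" %in% names(reviews)) {
    reviews$review_id <- seq_len(nrow(reviews))
  }
  for (col in c("title", "benefits", "side_effects", "comments")) {
    if (!col %in% names(reviews)) reviews[[col]] <- NA_character_
  }
  if (!"rating" %in% names(reviews)) reviews$rating <- NA_integer_
  prep_reviews(reviews, lexicon = lexicon)
}

# quick polarity-null quadruple row
quad <- function(effective, affected, relation,
                 unit_id = "r1_u1", review_id = 1L, field = "benefits",
                 completeness = "complete", route = "complete",
                 descriptor = NA_character_, n_negations = 0L,
                 quantifier = NA_character_, prior = "undesirable",
                 affected_sem_type = "sosy", affected_sem_group = "DISO",
                 polarity = NA_character_) {
  tibble::tibble(
    review_id = review_id, unit_id = unit_id, field = field,
    effective = effective, affected = affected, relation = relation,
    polarity = polarity, completeness = completeness, route = route,
    affected_sem_type = affected_sem_type,
    affected_sem_group = affected_sem_group,
    prior = prior, descriptor = descriptor,
    n_negations = n_negations, quantifier = quantifier
  )
}

empty_dkb <- function() {
  domain_kb(character(), character(), character(), character())
}

# Independent brute-force pattern miner (plain loops, no shared code with
# mine_patterns): type patterns are majority-polarity combinations supported
# by more than `threshold` KB entries; group patterns re-aggregate the
# *retained* type patterns.
brute_patterns <- function(kb, lexicon, threshold = 3) {
  type_of <- function(term) {
    j <- match(term, lexicon$term)
    if (is.na(j)) j <- match(sub("^.* ", "", term), lexicon$term)
    lexicon$sem_type[j]
  }
  group_of <- function(ty) lexicon$sem_group[match(ty, lexicon$sem_type)]
  et <- vapply(kb$effective, type_of, "")
  at <- vapply(kb$affected, type_of, "")
  keep <- !is.na(et) & !is.na(at)
  key <- paste(et[keep], at[keep], kb$relation[keep])
  pol <- kb$polarity[keep]
  majority_tally <- function(keys, pols, weights) {
    rows <- list()
    for (k in unique(keys)) {
      np <- sum(weights[keys == k & pols == "positive"])
      nn <- sum(weights[keys == k & pols == "negative"])
      if (np == nn) next
      supp <- max(np, nn)
      if (supp > threshold) {
        rows[[k]] <- list(
          key = k,
          polarity = if (np > nn) "positive" else "negative",
          support = supp
        )
      }
    }
    rows
  }
  type_rows <- majority_tally(key, pol, rep(1L, length(key)))
  gkeys <- character()
  gpols <- character()
  gw <- integer()
  for (t in type_rows) {
    parts <- strsplit(t$key, " ")[[1]]
    gkeys <- c(gkeys, paste(group_of(parts[1]), group_of(parts[2]), parts[3]))
    gpols <- c(gpols, t$polarity)
    gw <- c(gw, t$support)
  }
  group_rows <- majority_tally(gkeys, gpols, gw)
  as_tbl <- function(rows, level) {
    if (length(rows) == 0) {
      return(tibble::tibble(
        level = character(), effective_code = character(),
        affected_code = character(), relation = character(),
        polarity = character(), support = integer()
      ))
    }
    dplyr::bind_rows(purrr::map(rows, function(t) {
      parts <- strsplit(t$key, " ")[[1]]
      tibble::tibble(
        level = level, effective_code = parts[1], affected_code = parts[2],
        relation = parts[3], polarity = t$polarity,
        support = as.integer(t$support)
      )
    }))
  }
  dplyr::bind_rows(as_tbl(type_rows, "type"), as_tbl(group_rows, "group"))
}
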