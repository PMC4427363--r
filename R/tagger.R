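#' Rule-and-lexicon tagger
#'
#' Builds the bundled tokenizer / POS tagger / lemmatizer used throughout the
#' package. It is a deliberately small, deterministic engine: a closed lexicon
#' of verb forms and function words plus suffix rules, enough to analyse the
#' informal register of drug reviews and the vocabulary of the synthetic
#' fixtures. Every function that needs token-level analysis takes a `tagger`
#' argument, so a full statistical tagger can be substituted by supplying any
#' object with the same `$lexicon` layout.
#'
#' Coarse tagset: NOUN, VERB, AUX, ADJ, ADV, PRON, DET, ADP, CCONJ, SCONJ,
#' PART (negations), QUANT (increase/decrease quantifiers), NUM, PUNCT.
#' Verb entries carry `vform` (base, s3, past, part, ger); quantifier entries
#' carry `direction` (increase/decrease).
#'
#' @param extra_nouns Character vector of additional surface forms to treat as
#'   known nouns (their lemma is the singular form).
#' @return A list of class `okb_tagger` with a `lexicon` tibble
#'   (surface, pos, lemma, vform, direction).
#' @export
default_tagger <- function(extra_nouns = character()) {
  lexicon <- dplyr::bind_rows(
    verb_table(),
    function_word_table(),
    adjective_table(),
    noun_table(extra_nouns)
  )
  lex_df <- as.data.frame(lexicon, stringsAsFactors = FALSE)
  structure(
    list(
      lexicon = lexicon,
      index = split(seq_len(nrow(lex_df)), lex_df$surface),
      lex_df = lex_df
    ),
    class = "okb_tagger"
  )
}

# Regular + irregular verb paradigms. `past`/`part` default to regular -ed.
verb_table <- function() {
  reg <- function(base) {
    stem <- base
    ed <- if (stringr::str_detect(base, "e$")) paste0(base, "d") else paste0(base, "ed")
    ing <- if (stringr::str_detect(base, "e$") && !stringr::str_detect(base, "ee$")) {
      paste0(stringr::str_remove(base, "e$"), "ing")
    } else {
      paste0(base, "ing")
    }
    s3 <- if (stringr::str_detect(base, "(s|sh|ch|x|z)$")) paste0(base, "es") else paste0(base, "s")
    tibble::tibble(
      surface = c(base, s3, ed, ing),
      vform = c("base", "s3", "past", "ger"),
      lemma = base
    )
  }
  irr <- function(base, s3, past, part, ger) {
    tibble::tibble(
      surface = c(base, s3, past, part, ger),
      vform = c("base", "s3", "past", "part", "ger"),
      lemma = base
    )
  }
  bases <- c(
    "clear", "cause", "reduce", "alleviate", "cure", "improve", "relieve",
    "decrease", "increase", "help", "disappear", "worsen", "trigger", "calm",
    "ease", "induce", "prescribe", "miss", "skip", "love", "like",
    "experience", "work", "use", "suppose", "start", "stop", "want", "end",
    "happen", "return", "describe", "vanish", "fade", "settle", "bother",
    "disturb", "provoke", "elevate", "produce", "rid"
  )
  doubled <- tibble::tibble( # consonant-doubling regulars
    surface = c(
      "chap", "chaps", "chapped", "chapping",
      "dry", "dries", "dried", "drying",
      "stop", "stops", "stopped", "stopping"
    ),
    vform = rep(c("base", "s3", "past", "ger"), 3),
    lemma = rep(c("chap", "dry", "stop"), each = 4)
  )
  irregular <- dplyr::bind_rows(
    irr("go", "goes", "went", "gone", "going"),
    irr("take", "takes", "took", "taken", "taking"),
    irr("give", "gives", "gave", "given", "giving"),
    irr("get", "gets", "got", "gotten", "getting"),
    irr("say", "says", "said", "said", "saying"),
    irr("feel", "feels", "felt", "felt", "feeling"),
    irr("make", "makes", "made", "made", "making"),
    irr("come", "comes", "came", "come", "coming"),
    irr("sleep", "sleeps", "slept", "slept", "sleeping"),
    irr("see", "sees", "saw", "seen", "seeing"),
    irr("rid", "rids", "rid", "rid", "ridding")
  )
  out <- dplyr::bind_rows(purrr::map(bases, reg), doubled, irregular)
  # past forms of regular verbs double as participles
  parts <- out |>
    dplyr::filter(.data$vform == "past") |>
    dplyr::mutate(vform = "part")
  dplyr::bind_rows(out, parts) |>
    dplyr::distinct() |>
    dplyr::mutate(pos = "VERB", direction = NA_character_) |>
    dplyr::select("surface", "pos", "lemma", "vform", "direction")
}

function_word_table <- function() {
  row <- function(words, pos, lemma = words, direction = NA_character_) {
    tibble::tibble(
      surface = words, pos = pos, lemma = lemma,
      vform = NA_character_, direction = direction
    )
  }
  dplyr::bind_rows(
    row(c(
      "i", "you", "he", "she", "it", "they", "we", "me", "him", "her",
      "them", "us", "myself", "itself"
    ), "PRON"),
    row(c("my", "your", "his", "its", "their", "our"), "DET"),
    row(c(
      "the", "a", "an", "this", "that", "these", "those", "some", "any",
      "each", "every", "all", "both"
    ), "DET"),
    row(c("am", "is", "are", "was", "were", "be", "been", "being"), "AUX", "be"),
    row(c("do", "does", "did"), "AUX", "do"),
    row(c("have", "has", "had"), "AUX", "have"),
    row(c(
      "will", "would", "shall", "should", "can", "could", "may",
      "might", "must"
    ), "AUX"),
    row(c(
      "in", "on", "at", "with", "within", "of", "for", "to", "from", "by",
      "about", "after", "before", "during", "up", "down", "off", "over",
      "out", "into", "without"
    ), "ADP"),
    row(c("and", "but", "or", "nor", "yet"), "CCONJ"),
    row(c(
      "if", "unless", "because", "although", "though", "while", "when",
      "since", "whether", "so"
    ), "SCONJ"),
    row(c("not", "no", "never", "n't", "none", "nothing"), "PART"),
    row(c("less", "fewer"), "QUANT", direction = "decrease"),
    row(c("more", "extra"), "QUANT", direction = "increase"),
    row(c(
      "very", "really", "quite", "almost", "completely", "pretty", "still",
      "just", "definitely", "often", "usually", "now", "then", "here",
      "too", "also", "daily", "occasionally", "considerably",
      "significantly", "quickly", "away", "back", "again", "well"
    ), "ADV")
  )
}

adjective_table <- function() {
  adj <- c(
    "dry", "clear", "chapped", "cystic", "occasional", "extensive",
    "lasting", "great", "good", "bad", "horrible", "amazing", "helpful",
    "severe", "mild", "sore", "itchy", "effective", "dangerous", "high",
    "low", "fast", "new", "right", "happy", "dizzy", "tired", "smooth",
    "friendly", "long", "slow", "tasty", "expensive", "cheap"
  )
  tibble::tibble(
    surface = adj, pos = "ADJ", lemma = adj,
    vform = NA_character_, direction = NA_character_
  )
}

noun_table <- function(extra = character()) {
  sing <- c(
    "acne", "skin", "pain", "headache", "heartburn", "anxiety", "migraine",
    "depression", "nausea", "dizziness", "insomnia", "rash", "confusion",
    "weakness", "muscle", "palpitation", "heart", "drowsiness", "redness",
    "breakout", "lip", "nose", "stomach", "cramp", "irritation", "dryness",
    "clearing", "relief", "peeling", "flaking", "vision", "sleep",
    "doctor", "month", "week", "day", "night", "year", "course", "amount",
    "dose", "food", "drug", "medication", "medicine", "pill", "tablet",
    "symptom", "effect", "bleeding", "overdose", "wallet", "purse",
    "packaging", "value", "money", "service", "waiter", "restaurant",
    "meal", "price", "battery", "screen", "product", "phone", "camera",
    "fever", "swelling", "fatigue", "itching", "bloating", "appetite",
    "energy", "mood", "infection", "condition", "time", "result",
    tolower(extra)
  )
  sing <- unique(sing)
  plur <- dplyr::case_when(
    stringr::str_detect(sing, "(s|sh|ch|x|z)$") ~ paste0(sing, "es"),
    stringr::str_detect(sing, "[^aeiou]y$") ~ stringr::str_replace(sing, "y$", "ies"),
    TRUE ~ paste0(sing, "s")
  )
  tibble::tibble(
    surface = c(sing, plur), pos = "NOUN", lemma = c(sing, sing),
    vform = NA_character_, direction = NA_character_
  ) |>
    dplyr::distinct(.data$surface, .keep_all = TRUE)
}

#' Tokenize and tag one text unit
#'
#' Splits `text` into word and punctuation tokens with 0-based half-open
#' character spans, then assigns a coarse POS tag, lemma, verb form and
#' quantifier direction from the tagger lexicon. Ambiguous surface forms
#' (e.g. "dry" ADJ vs VERB, "sleep" NOUN vs VERB) are resolved by local
#' context rules; unknown words default to NOUN with a plural-stripping
#' lemma rule.
#'
#' @param text A single string.
#' @param tagger A tagger from [default_tagger()].
#' @return Tibble with columns surface, lemma, pos, vform, direction,
#'   start, end (character offsets, 0-based half-open).
#' @export
tokenize_text <- function(text, tagger = default_tagger()) {
  stopifnot(length(text) == 1)
  if (is.na(text) || !nzchar(text)) {
    return(tibble::tibble(
      surface = character(), lemma = character(), pos = character(),
      vform = character(), direction = character(),
      start = integer(), end = integer()
    ))
  }
  pat <- "[A-Za-z]+(?:'[A-Za-z]+)?|[0-9]+(?:[./-][0-9]+)*|[^\\sA-Za-z0-9]"
  loc <- stringr::str_locate_all(text, pat)[[1]]
  surface <- stringr::str_sub(text, loc[, 1], loc[, 2])
  toks <- tibble::tibble(
    surface = surface,
    start = as.integer(loc[, 1] - 1L),
    end = as.integer(loc[, 2])
  )
  n <- nrow(toks)
  lower <- tolower(surface)
  lex <- tagger$lex_df %||% as.data.frame(tagger$lexicon)
  idx <- tagger$index %||% split(seq_len(nrow(lex)), lex$surface)
  pos <- character(n); lemma <- character(n)
  vform <- rep(NA_character_, n); direction <- rep(NA_character_, n)
  cand <- purrr::map(lower, function(w) {
    j <- idx[[w]]
    if (is.null(j)) lex[0, , drop = FALSE] else lex[j, , drop = FALSE]
  })
  base_pos <- purrr::map_chr(cand, \(m) if (nrow(m) > 0) m$pos[1] else NA_character_)
  is_word <- stringr::str_detect(surface, "^[A-Za-z]")
  for (k in seq_len(n)) {
    if (!is_word[k]) {
      pos[k] <- if (stringr::str_detect(surface[k], "^[0-9]")) "NUM" else "PUNCT"
      lemma[k] <- surface[k]
      next
    }
    m <- cand[[k]]
    if (nrow(m) == 0) { # unknown -> NOUN, strip simple plural
      pos[k] <- "NOUN"
      lemma[k] <- strip_plural(lower[k])
      next
    }
    classes <- unique(m$pos)
    pick <- if (length(classes) == 1) classes else {
      resolve_ambiguous(k, classes, base_pos, cand, lower)
    }
    row <- m[m$pos == pick, , drop = FALSE][1, ]
    pos[k] <- row$pos; lemma[k] <- row$lemma
    vform[k] <- row$vform; direction[k] <- row$direction
  }
  toks$lemma <- lemma; toks$pos <- pos
  toks$vform <- vform; toks$direction <- direction
  toks[, c("surface", "lemma", "pos", "vform", "direction", "start", "end")]
}

strip_plural <- function(w) {
  if (stringr::str_detect(w, "ies$") && nchar(w) > 4) {
    stringr::str_replace(w, "ies$", "y")
  } else if (stringr::str_detect(w, "(ss|us|is)$")) {
    w
  } else if (stringr::str_detect(w, "(ches|shes|xes|zes|ses)$")) {
    stringr::str_remove(w, "es$")
  } else if (stringr::str_detect(w, "s$") && nchar(w) > 3) {
    stringr::str_remove(w, "s$")
  } else {
    w
  }
}

# Context rules for surface forms listed under more than one POS.
resolve_ambiguous <- function(k, classes, base_pos, cand, lower) {
  nxt <- if (k < length(base_pos)) base_pos[k + 1] else NA_character_
  nxt_lower <- if (k < length(lower)) lower[k + 1] else NA_character_
  prv <- if (k > 1) base_pos[k - 1] else NA_character_
  if ("ADJ" %in% classes && "VERB" %in% classes) {
    vrows <- cand[[k]]
    vf <- vrows$vform[vrows$pos == "VERB"][1]
    # predicate adjective after "be": base form -> ADJ ("skin is clear"),
    # inflected form -> passive VERB ("skin was cleared")
    if (identical(prv, "AUX") || identical(prv, "ADV")) {
      return(if (identical(vf, "base")) "ADJ" else "VERB")
    }
    if (identical(nxt, "NOUN") || identical(nxt, "ADJ")) return("ADJ")
    return("VERB")
  }
  if ("NOUN" %in% classes && "VERB" %in% classes) {
    if (identical(prv, "ADP") || identical(prv, "DET") || identical(prv, "ADJ")) {
      return("NOUN")
    }
    # gerund used as a nominalization ("Clearing of acne") unless in a
    # progressive ("was clearing")
    vrows <- cand[[k]]
    vf <- vrows$vform[vrows$pos == "VERB"][1]
    if (identical(vf, "ger") && !identical(prv, "AUX")) {
      return("NOUN")
    }
    return("VERB")
  }
  classes[1]
}

#' @keywords internal
first_main_verb_index <- function(tokens) {
  idx <- which(tokens$pos == "VERB" &
    tokens$vform %in% c("base", "s3", "past", "part"))
  if (length(idx) == 0) {
    return(NA_integer_)
  }
  # skip infinitives ("to alleviate" keeps its matrix verb elsewhere)
  keep <- purrr::map_lgl(idx, function(i) {
    !(i > 1 && tolower(tokens$surface[i - 1]) == "to" &&
      tokens$vform[i] == "base")
  })
  idx <- idx[keep]
  if (length(idx) == 0) NA_integer_ else idx[1]
}

# TRUE when the verb at index i heads a passive construction:
# a form of "be" precedes it (allowing intervening adverbs/negation)
# and the verb form is a past/participle.
is_passive_at <- function(tokens, i) {
  if (is.na(i) || !(tokens$vform[i] %in% c("past", "part"))) {
    return(FALSE)
  }
  j <- i - 1
  while (j >= 1 && tokens$pos[j] %in% c("ADV", "PART")) j <- j - 1
  j >= 1 && tokens$pos[j] == "AUX" && identical(tokens$lemma[j], "be")
}
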