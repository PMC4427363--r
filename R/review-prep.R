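#' Read structured drug reviews
#'
#' Reviews are stored one record per line as JSON objects with keys
#' `drug`, `title`, `rating`, `benefits`, `side_effects`, `comments`
#' (UTF-8; the layout of druglib-style review sites, where benefits and
#' side effects are entered in separate fields).
#'
#' @param path Path to a line-delimited review file.
#' @return A tibble with one row per review: `review_id`, `drug`, `title`,
#'   `rating` (integer, `NA` when absent) and the three text fields.
#' @export
read_reviews <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty review file: ", path, call. = FALSE)
    return(empty_reviews())
  }
  recs <- purrr::imap(lines, function(ln, i) {
    rec <- tryCatch(jsonlite::fromJSON(ln), error = function(e) {
      stop("malformed review record at line ", i, ": ", conditionMessage(e),
        call. = FALSE
      )
    })
    if (is.null(rec$drug) || !nzchar(trimws(as.character(rec$drug)[1]))) {
      stop("review record at line ", i, " has no drug name", call. = FALSE)
    }
    fields <- c("benefits", "side_effects", "comments")
    if (all(purrr::map_lgl(fields, \(f) is.null(rec[[f]]) ||
      !nzchar(trimws(as.character(rec[[f]])[1]))))) {
      stop("review record at line ", i, " has no text field", call. = FALSE)
    }
    chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)[1]
    tibble::tibble(
      review_id = i,
      drug = chr1(rec$drug),
      title = chr1(rec$title),
      rating = if (is.null(rec$rating)) NA_integer_ else as.integer(rec$rating)[1],
      benefits = chr1(rec$benefits),
      side_effects = chr1(rec$side_effects),
      comments = chr1(rec$comments)
    )
  })
  dplyr::bind_rows(recs)
}

empty_reviews <- function() {
  tibble::tibble(
    review_id = integer(), drug = character(), title = character(),
    rating = integer(), benefits = character(), side_effects = character(),
    comments = character()
  )
}

#' Write reviews in the line-delimited record format
#'
#' @param reviews A reviews tibble as returned by [read_reviews()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_reviews <- function(reviews, path) {
  lines <- purrr::pmap_chr(reviews, function(review_id, drug, title, rating,
                                             benefits, side_effects, comments, ...) {
    rec <- list(
      drug = drug, title = title, rating = rating,
      benefits = benefits, side_effects = side_effects, comments = comments
    )
    rec <- rec[!purrr::map_lgl(rec, \(x) is.null(x) || all(is.na(x)))]
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

#' Segment review fields into simple sentence units
#'
#' Each populated field is sentence-segmented, then every compound sentence is
#' split at clause-level coordinating conjunctions ("and"/"but"-like) into
#' simple units. A split only happens when both sides contain their own verbal
#' material, so coordinated noun phrases ("confusion, and lasting muscle
#' weakness") stay together and yield several affected entities in one unit.
#' The connecting conjunction is recorded on the second unit (`conj`,
#' normalised to "and" or "but") together with the id of the unit it links to
#' (`conj_with`), for later polarity propagation.
#'
#' @param reviews A reviews tibble.
#' @param tagger A tagger from [default_tagger()].
#' @return A units tibble: `review_id`, `drug`, `rating`, `unit_id`, `field`,
#'   `index_in_review`, `text`, `conj`, `conj_with`, `is_phrase` and a
#'   `tokens` list-column.
#' @export
segment_units <- function(reviews, tagger = default_tagger()) {
  fields <- c("benefits", "side_effects", "comments")
  rows <- purrr::pmap(reviews, function(review_id, drug, rating, ...) {
    dots <- list(...)
    idx <- 0L
    out <- list()
    for (f in fields) {
      txt <- dots[[f]]
      if (is.null(txt) || is.na(txt) || !nzchar(trimws(txt))) next
      for (sent in split_sentences(txt)) {
        clauses <- split_clauses(sent, tagger)
        for (j in seq_len(nrow(clauses))) {
          idx <- idx + 1L
          out[[length(out) + 1L]] <- tibble::tibble(
            review_id = review_id, drug = drug, rating = rating,
            field = f, index_in_review = idx,
            text = clauses$text[j],
            conj = clauses$conj[j]
          )
        }
      }
    }
    dplyr::bind_rows(out)
  })
  units <- dplyr::bind_rows(rows)
  if (nrow(units) == 0) {
    return(empty_units())
  }
  units <- units |>
    dplyr::mutate(
      unit_id = paste0("r", .data$review_id, "_u", .data$index_in_review),
      conj_with = ifelse(is.na(.data$conj), NA_character_,
        paste0("r", .data$review_id, "_u", .data$index_in_review - 1L)
      )
    )
  retokenize_units(units, tagger)
}

empty_units <- function() {
  tibble::tibble(
    review_id = integer(), drug = character(), rating = integer(),
    field = character(), index_in_review = integer(), text = character(),
    conj = character(), unit_id = character(), conj_with = character(),
    tokens = list(), is_phrase = logical()
  )
}

retokenize_units <- function(units, tagger) {
  units$tokens <- purrr::map(units$text, tokenize_text, tagger = tagger)
  units$is_phrase <- purrr::map_lgl(
    units$tokens,
    \(tk) is.na(first_main_verb_index(tk))
  )
  units |>
    dplyr::select(
      "review_id", "drug", "rating", "unit_id", "field",
      "index_in_review", "text", "conj", "conj_with", "is_phrase", "tokens"
    )
}

split_sentences <- function(text) {
  text <- stringr::str_replace_all(text, "\\s+", " ")
  parts <- stringr::str_split(text, "(?<=[.!?])\\s+")[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# Split one sentence at clause-level coordination. Returns tibble(text, conj).
split_clauses <- function(sentence, tagger) {
  toks <- tokenize_text(sentence, tagger)
  cc <- which(toks$pos == "CCONJ" & toks$lemma %in% c("and", "but", "or", "yet"))
  pieces <- list(list(text = sentence, conj = NA_character_, toks = toks))
  for (i in rev(cc)) { # rightmost first so earlier offsets stay valid
    has_verbal <- function(tk) any(tk$pos %in% c("VERB", "AUX"))
    left <- toks[seq_len(i - 1), , drop = FALSE]
    right <- toks[seq(i + 1, nrow(toks)), , drop = FALSE]
    if (nrow(left) == 0 || nrow(right) < 2) next
    if (!has_verbal(left) || !has_verbal(right)) next
    cur <- pieces[[1]]
    left_txt <- trimws(stringr::str_sub(cur$text, 1, toks$start[i]))
    left_txt <- stringr::str_remove(left_txt, "[,;]\\s*$")
    right_txt <- trimws(stringr::str_sub(cur$text, toks$end[i] + 1))
    conj_norm <- if (toks$lemma[i] %in% c("but", "yet")) "but" else "and"
    pieces[[1]] <- list(text = left_txt, conj = cur$conj, toks = NULL)
    pieces <- append(pieces,
      list(list(text = right_txt, conj = conj_norm, toks = NULL)),
      after = 1
    )
    toks <- toks[seq_len(i - 1), , drop = FALSE]
  }
  tibble::tibble(
    text = purrr::map_chr(pieces, "text"),
    conj = purrr::map_chr(pieces, "conj")
  )
}

#' Discard imperative and conditional units
#'
#' Imperatives (a leading base-form verb with no preceding subject noun or
#' pronoun) and conditionals (a marker from `conditional_markers` at clause
#' start, or a conditional modal anywhere) express instructions and
#' hypotheticals rather than experienced effects, so they are removed before
#' extraction. Removals are reported with counts and attached as the
#' `"removed"` attribute of the result.
#'
#' @param units A units tibble from [segment_units()].
#' @param conditional_markers Markers that flag a conditional clause.
#'   Subordinators must be clause-initial; modals ("would", "should") match
#'   anywhere.
#' @param quiet Suppress the removal-count message.
#' @return The retained units, with attribute `removed` (tibble of
#'   `unit_id`, `reason`).
#' @export
filter_declaratives <- function(units,
                                conditional_markers = c("if", "unless", "would"),
                                quiet = FALSE) {
  if (nrow(units) == 0) {
    out <- units
    attr(out, "removed") <- tibble::tibble(unit_id = character(), reason = character())
    return(out)
  }
  reason <- purrr::map_chr(units$tokens, function(tk) {
    w <- tk[tk$pos != "PUNCT", , drop = FALSE]
    if (nrow(w) == 0) {
      return(NA_character_)
    }
    modals <- intersect(conditional_markers, c("would", "should", "could", "might"))
    initial <- setdiff(conditional_markers, modals)
    if (tolower(w$surface[1]) %in% initial) {
      return("conditional")
    }
    if (any(tolower(w$surface) %in% modals)) {
      return("conditional")
    }
    # leading base-form verb, no subject before it -> imperative
    first_content <- which(!w$pos %in% c("ADV", "PART"))[1]
    if (!is.na(first_content) &&
      w$pos[first_content] == "VERB" &&
      identical(w$vform[first_content], "base")) {
      return("imperative")
    }
    NA_character_
  })
  removed <- tibble::tibble(unit_id = units$unit_id, reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
  if (!quiet && nrow(removed) > 0) {
    counts <- table(removed$reason)
    message(
      "filter_declaratives removed ", nrow(removed), " unit(s): ",
      paste(names(counts), counts, sep = "=", collapse = ", ")
    )
  }
  out <- units[is.na(reason), , drop = FALSE]
  attr(out, "removed") <- removed
  out
}

#' Resolve subject pronouns against the review's drug
#'
#' The bundled resolver substitutes the bare deictics "it", "this drug",
#' "this medication"/"this medicine" in subject position with the nearest
#' preceding drug-type entity mention in the review, falling back to the
#' review's own drug name. Gendered third-person pronouns ("he", "she",
#' "they") have no plausible drug antecedent under this heuristic, so they are
#' left in place and flagged. Pass a different `resolver` function
#' (same signature) to plug in a full coreference engine.
#'
#' @param units A units tibble.
#' @param tagger Tagger used to re-tokenize substituted units.
#' @param lexicon Optional semantic lexicon ([read_semantic_lexicon()]); when
#'   supplied, drug-type mentions in preceding units are preferred antecedents.
#' @param resolver Resolver function `(unit_tokens, antecedent) -> list(text,
#'   flagged)`; the default implements the heuristic above.
#' @return Units with substituted text/tokens and a `pron_unresolved` count
#'   column.
#' @export
resolve_pronouns <- function(units, tagger = default_tagger(), lexicon = NULL,
                             resolver = NULL) {
  if (nrow(units) == 0) {
    units$pron_unresolved <- integer()
    return(units)
  }
  resolver <- resolver %||% default_pronoun_resolver
  units <- units |> dplyr::arrange(.data$review_id, .data$index_in_review)
  out_text <- units$text
  flagged <- integer(nrow(units))
  changed <- logical(nrow(units))
  for (rid in unique(units$review_id)) {
    rows <- which(units$review_id == rid)
    seen_drugs <- character()
    for (i in rows) {
      antecedent <- if (length(seen_drugs) > 0) {
        seen_drugs[length(seen_drugs)]
      } else {
        units$drug[i]
      }
      res <- resolver(units$tokens[[i]], antecedent)
      if (!identical(res$text, NA_character_)) {
        out_text[i] <- res$text
        changed[i] <- TRUE
      }
      flagged[i] <- res$flagged
      if (!is.null(lexicon)) {
        drug_terms <- lexicon$term[lexicon$sem_type %in% attr(lexicon, "drug_types")]
        hits <- intersect(tolower(units$tokens[[i]]$lemma), drug_terms)
        # keep original casing from the unit text
        for (h in hits) {
          j <- which(tolower(units$tokens[[i]]$lemma) == h)[1]
          seen_drugs <- c(seen_drugs, units$tokens[[i]]$surface[j])
        }
      } else if (any(tolower(units$tokens[[i]]$surface) == tolower(units$drug[i]))) {
        seen_drugs <- c(seen_drugs, units$drug[i])
      }
    }
  }
  units$text <- out_text
  units$pron_unresolved <- flagged
  to_fix <- which(changed)
  if (length(to_fix) > 0) {
    units$tokens[to_fix] <- purrr::map(units$text[to_fix], tokenize_text,
      tagger = tagger
    )
    units$is_phrase[to_fix] <- purrr::map_lgl(
      units$tokens[to_fix], \(tk) is.na(first_main_verb_index(tk))
    )
  }
  units
}

# Substitute subject-position deictics; returns list(text = new text or NA,
# flagged = count of unresolved subject pronouns).
default_pronoun_resolver <- function(tokens, antecedent) {
  if (nrow(tokens) == 0) {
    return(list(text = NA_character_, flagged = 0L))
  }
  verbal <- which(tokens$pos %in% c("VERB", "AUX"))
  subj_limit <- if (length(verbal) > 0) verbal[1] - 1L else nrow(tokens)
  if (subj_limit < 1) {
    return(list(text = NA_character_, flagged = 0L))
  }
  flagged <- 0L
  repl_start <- NA_integer_
  repl_end <- NA_integer_
  for (k in seq_len(subj_limit)) {
    lem <- tolower(tokens$lemma[k])
    if (tokens$pos[k] == "PRON" && lem == "it") {
      repl_start <- tokens$start[k]; repl_end <- tokens$end[k]
      break
    }
    if (tokens$pos[k] == "DET" && lem == "this" && k < nrow(tokens) &&
      tolower(tokens$lemma[k + 1]) %in% c("drug", "medication", "medicine")) {
      repl_start <- tokens$start[k]; repl_end <- tokens$end[k + 1]
      break
    }
    if (tokens$pos[k] == "PRON" && lem %in% c("he", "she", "they")) {
      flagged <- flagged + 1L
    }
  }
  if (is.na(repl_start)) {
    return(list(text = NA_character_, flagged = flagged))
  }
  # reconstruct the text from the token spans
  full <- reconstruct_text(tokens)
  new <- paste0(
    substr(full, 1, repl_start),
    antecedent,
    substr(full, repl_end + 1, nchar(full))
  )
  list(text = new, flagged = flagged)
}

reconstruct_text <- function(tokens) {
  if (nrow(tokens) == 0) {
    return("")
  }
  total <- max(tokens$end)
  out <- strrep(" ", total)
  for (k in seq_len(nrow(tokens))) {
    substr(out, tokens$start[k] + 1, tokens$end[k]) <- tokens$surface[k]
  }
  out
}

#' Preprocess reviews end to end
#'
#' Convenience wrapper: [segment_units()], [filter_declaratives()],
#' [resolve_pronouns()].
#'
#' @inheritParams segment_units
#' @inheritParams filter_declaratives
#' @inheritParams resolve_pronouns
#' @return A preprocessed units tibble.
#' @export
prep_reviews <- function(reviews, tagger = default_tagger(), lexicon = NULL,
                         conditional_markers = c("if", "unless", "would"),
                         quiet = TRUE) {
  reviews |>
    segment_units(tagger) |>
    filter_declaratives(conditional_markers, quiet = quiet) |>
    resolve_pronouns(tagger, lexicon)
}
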