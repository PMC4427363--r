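#' Construct a semantic lexicon
#'
#' The lexicon maps lowercase lemma phrases to fine-grained semantic type
#' codes and coarse semantic group codes, in the style of the UMLS (e.g. type
#' "sosy" Sign or Symptom within group "DISO" Disorders; "phsu" Pharmacologic
#' Substance within "CHEM" Chemicals & Drugs). A fourth attribute records the
#' desirability prior of the concept (needed by the quantifier valence-shifter
#' rules); terms in the DISO group default to "undesirable", everything else
#' to "neutral".
#'
#' @param term Character, lowercase lemma phrases.
#' @param sem_type Character, semantic type code per term.
#' @param sem_group Character, semantic group code per type.
#' @param prior Optional desirability prior per term
#'   (`desirable`/`undesirable`/`neutral`).
#' @param drug_types Type codes treated as effective-entity (drug) types.
#' @return A tibble of class `semantic_lexicon` with attribute `drug_types`.
#' @export
semantic_lexicon <- function(term, sem_type, sem_group, prior = NULL,
                             drug_types = "phsu") {
  term <- tolower(term)
  stopifnot(length(term) == length(sem_type), length(term) == length(sem_group))
  if (is.null(prior)) {
    prior <- ifelse(sem_group == "DISO", "undesirable", "neutral")
  }
  stopifnot(all(prior %in% c("desirable", "undesirable", "neutral")))
  # a type code must map to a single group
  map <- unique(tibble::tibble(sem_type = sem_type, sem_group = sem_group))
  if (anyDuplicated(map$sem_type)) {
    stop("semantic type mapped to more than one group: ",
      paste(map$sem_type[duplicated(map$sem_type)], collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    term = term, sem_type = sem_type, sem_group = sem_group, prior = prior
  ) |>
    dplyr::distinct(.data$term, .keep_all = TRUE) |>
    dplyr::mutate(n_words = stringr::str_count(.data$term, "\\S+"))
  structure(out,
    drug_types = drug_types,
    class = c("semantic_lexicon", class(out))
  )
}

#' Read / write a semantic lexicon
#'
#' Tab-delimited table with columns term, sem_type, sem_group and an optional
#' prior column.
#'
#' @param path File path.
#' @param drug_types Type codes treated as drug types.
#' @return [read_semantic_lexicon()] returns a `semantic_lexicon`;
#'   [write_semantic_lexicon()] returns `path` invisibly.
#' @export
read_semantic_lexicon <- function(path, drug_types = "phsu") {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  semantic_lexicon(tb$term, tb$sem_type, tb$sem_group,
    prior = if ("prior" %in% names(tb)) tb$prior else NULL,
    drug_types = drug_types
  )
}

#' @rdname read_semantic_lexicon
#' @param lexicon A `semantic_lexicon`.
#' @export
write_semantic_lexicon <- function(lexicon, path) {
  readr::write_tsv(
    lexicon[, c("term", "sem_type", "sem_group", "prior")], path
  )
  invisible(path)
}

#' Tag entity mentions in sentence units
#'
#' Greedy longest-match of lemma n-grams against the lexicon, case-insensitive;
#' shorter matches overlapping a longer one are suppressed ("muscle weakness"
#' wins over "muscle"). Each match becomes one mention with its semantic
#' type/group; roles are assigned from the typing: `effective` for drug-typed
#' mentions, `affected` for mentions whose group is among the selected
#' affected groups, `other` otherwise. Terms absent from the lexicon are
#' simply left untagged.
#'
#' @param units A units tibble (needs `unit_id` and `tokens`).
#' @param lexicon A [semantic_lexicon()].
#' @param affected_groups Character vector of selected affected semantic
#'   groups (see [select_affected_groups()]); `NULL` means none selected yet.
#' @return A mentions tibble: unit/review identifiers, `surface`, `lemma`,
#'   `sem_type`, `sem_group`, `prior`, char span (`start`, `end`), token span
#'   (`tok_first`, `tok_last`) and `role`.
#' @export
tag_entities <- function(units, lexicon, affected_groups = NULL) {
  stopifnot(inherits(lexicon, "semantic_lexicon"))
  drug_types <- attr(lexicon, "drug_types")
  max_len <- max(lexicon$n_words, 1L)
  per_unit <- purrr::pmap(
    list(units$unit_id, units$review_id, units$field, units$tokens),
    function(unit_id, review_id, field, tokens) {
      m <- match_mentions(tokens, lexicon, max_len)
      if (nrow(m) == 0) {
        return(NULL)
      }
      m$unit_id <- unit_id
      m$review_id <- review_id
      m$field <- field
      m
    }
  )
  mentions <- dplyr::bind_rows(per_unit)
  if (nrow(mentions) == 0) {
    return(empty_mentions())
  }
  mentions |>
    dplyr::mutate(
      role = dplyr::case_when(
        .data$sem_type %in% drug_types ~ "effective",
        .data$sem_group %in% (affected_groups %||% character()) ~ "affected",
        TRUE ~ "other"
      )
    ) |>
    dplyr::select(
      "unit_id", "review_id", "field", "surface", "lemma", "sem_type",
      "sem_group", "prior", "start", "end", "tok_first", "tok_last", "role"
    )
}

empty_mentions <- function() {
  tibble::tibble(
    unit_id = character(), review_id = integer(), field = character(),
    surface = character(), lemma = character(), sem_type = character(),
    sem_group = character(), prior = character(), start = integer(),
    end = integer(), tok_first = integer(), tok_last = integer(),
    role = character()
  )
}

match_mentions <- function(tokens, lexicon, max_len) {
  word_idx <- which(tokens$pos != "PUNCT")
  n <- length(word_idx)
  hits_i <- integer(0)
  hits_len <- integer(0)
  hits_row <- integer(0)
  i <- 1
  while (i <= n) {
    hit_len <- 0L
    for (len in seq(min(max_len, n - i + 1L), 1L)) {
      ks <- word_idx[i:(i + len - 1L)]
      phrase <- tolower(paste(tokens$lemma[ks], collapse = " "))
      j <- match(phrase, lexicon$term)
      if (!is.na(j)) {
        hits_i <- c(hits_i, i)
        hits_len <- c(hits_len, len)
        hits_row <- c(hits_row, j)
        hit_len <- len
        break
      }
    }
    i <- i + max(hit_len, 1L)
  }
  if (length(hits_i) == 0) {
    return(tibble::tibble())
  }
  first <- word_idx[hits_i]
  last <- word_idx[hits_i + hits_len - 1L]
  span_txt <- function(fun) {
    purrr::map2_chr(hits_i, hits_len, function(a, len) {
      ks <- word_idx[a:(a + len - 1L)]
      paste(fun(ks), collapse = " ")
    })
  }
  tibble::tibble(
    surface = span_txt(\(ks) tokens$surface[ks]),
    lemma = tolower(span_txt(\(ks) tokens$lemma[ks])),
    sem_type = lexicon$sem_type[hits_row],
    sem_group = lexicon$sem_group[hits_row],
    prior = lexicon$prior[hits_row],
    start = tokens$start[first],
    end = tokens$end[last],
    tok_first = first,
    tok_last = last
  )
}
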