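#' Domain knowledge base of known drug effects
#'
#' A DomainKB row records that `effect_term` is a known benefit or side effect
#' of `drug`, with the semantic type of the effect term and an optional
#' relation verb lemma. `(drug, effect_term, effect_kind)` must be unique.
#'
#' @param drug,effect_term,effect_kind,sem_type Character vectors.
#' @param relation Optional relation verb lemma (`NA` = any).
#' @return A tibble of class `domain_kb`.
#' @export
domain_kb <- function(drug, effect_term, effect_kind, sem_type,
                      relation = NA_character_) {
  stopifnot(all(effect_kind %in% c("benefit", "side_effect")))
  out <- tibble::tibble(
    drug = tolower(drug), effect_term = tolower(effect_term),
    effect_kind = effect_kind, sem_type = sem_type,
    relation = tolower(relation)
  )
  if (anyDuplicated(out[, c("drug", "effect_term", "effect_kind")])) {
    stop("duplicate (drug, effect_term, effect_kind) records in DomainKB",
      call. = FALSE
    )
  }
  structure(out, class = c("domain_kb", class(out)))
}

#' @rdname domain_kb
#' @param path File path (tab-delimited, 5 columns).
#' @export
read_domain_kb <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  domain_kb(tb$drug, tb$effect_term, tb$effect_kind, tb$sem_type,
    relation = if ("relation" %in% names(tb)) tb$relation else NA_character_
  )
}

#' @rdname domain_kb
#' @param kb A `domain_kb`.
#' @export
write_domain_kb <- function(kb, path) {
  readr::write_tsv(tibble::as_tibble(kb), path)
  invisible(path)
}

#' Counted relation-triple store
#'
#' A local store of counted (arg0, predicate, arg1) relations that plays the
#' role of a live open-information-extraction service: missing-subject
#' resolution queries it for how often a candidate subject was seen with a
#' given verb and affected entity on the open web. Matching is on lemmas;
#' lookups of absent keys return 0.
#'
#' @param arg0,predicate,arg1 Character vectors (lemmas).
#' @param count Positive integer counts.
#' @return A tibble of class `triple_store`.
#' @export
triple_store <- function(arg0 = character(), predicate = character(),
                         arg1 = character(), count = integer()) {
  stopifnot(all(count >= 1))
  out <- tibble::tibble(
    arg0 = tolower(arg0), predicate = tolower(predicate),
    arg1 = tolower(arg1), count = as.integer(count)
  ) |>
    dplyr::summarise(count = sum(.data$count),
      .by = c("arg0", "predicate", "arg1")
    )
  structure(out, class = c("triple_store", class(out)))
}

#' @rdname triple_store
#' @param path File path (tab-delimited: arg0, predicate, arg1, count).
#' @export
read_triple_store <- function(path) {
  tb <- readr::read_tsv(path, col_types = "ccci")
  triple_store(tb$arg0, tb$predicate, tb$arg1, tb$count)
}

#' @rdname triple_store
#' @param store A `triple_store`.
#' @export
write_triple_store <- function(store, path) {
  readr::write_tsv(tibble::as_tibble(store), path)
  invisible(path)
}

#' Count triples matching (arg0, predicate, arg1)
#'
#' Vectorized over `arg0`; absent keys count 0.
#'
#' @param store A [triple_store()].
#' @param arg0 Candidate subject lemmas.
#' @param predicate Verb lemma (length 1).
#' @param arg1 Affected-entity lemma (length 1).
#' @return Integer vector of counts, one per `arg0`.
#' @export
triple_count <- function(store, arg0, predicate, arg1) {
  sub <- store[store$predicate == tolower(predicate) &
    store$arg1 == tolower(arg1), , drop = FALSE]
  out <- sub$count[match(tolower(arg0), sub$arg0)]
  out[is.na(out)] <- 0L
  out
}

#' Read / write an OpinionKB
#'
#' Line-delimited JSON records with fields effective, affected, relation,
#' polarity, confidence, support.
#'
#' @param kb An `opinion_kb` from [build_opinion_kb()].
#' @param path File path.
#' @return [read_opinion_kb()] returns an `opinion_kb` tibble.
#' @export
write_opinion_kb <- function(kb, path) {
  write_jsonl(tibble::as_tibble(kb), path)
  invisible(path)
}

#' @rdname write_opinion_kb
#' @export
read_opinion_kb <- function(path) {
  out <- read_jsonl(path, c(
    effective = "character", affected = "character", relation = "character",
    polarity = "character", confidence = "numeric", support = "integer"
  ))
  structure(out, class = c("opinion_kb", class(out)))
}

#' Read / write mined polarity patterns
#'
#' Tab-delimited table: level, effective_code, affected_code, relation,
#' polarity, support.
#'
#' @param patterns A patterns tibble from [mine_patterns()].
#' @param path File path.
#' @return [read_patterns()] returns the patterns tibble.
#' @export
write_patterns <- function(patterns, path) {
  readr::write_tsv(tibble::as_tibble(patterns), path)
  invisible(path)
}

#' @rdname write_patterns
#' @export
read_patterns <- function(path) {
  readr::read_tsv(path, col_types = "ccccci")
}

# --- line-delimited JSON helpers ------------------------------------------

write_jsonl <- function(df, path) {
  if (nrow(df) == 0) {
    readr::write_lines(character(), path)
    return(invisible(path))
  }
  lines <- purrr::map_chr(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, , drop = FALSE])
    rec <- purrr::map(rec, \(x) if (is.list(x)) x[[1]] else x)
    jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null", na = "null")
  })
  readr::write_lines(lines, path)
  invisible(path)
}

read_jsonl <- function(path, col_types) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::as_tibble(purrr::map(col_types, \(ty) vector(ty, 0)))
  if (length(lines) == 0) {
    return(empty)
  }
  recs <- purrr::imap(lines, function(ln, i) {
    rec <- tryCatch(jsonlite::fromJSON(ln, simplifyVector = FALSE),
      error = function(e) {
        stop("malformed record at line ", i, ": ", conditionMessage(e),
          call. = FALSE
        )
      }
    )
    missing <- setdiff(names(col_types), names(rec))
    if (length(missing) > 0) {
      stop("record at line ", i, " is missing field(s): ",
        paste(missing, collapse = ", "),
        call. = FALSE
      )
    }
    tibble::as_tibble(purrr::imap(col_types, function(ty, nm) {
      v <- rec[[nm]]
      if (is.null(v)) {
        return(vector(ty, 1)[NA])
      }
      if (is.list(v)) {
        return(list(v))
      }
      methods::as(v, ty)
    }))
  })
  dplyr::bind_rows(recs)
}
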