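#' Build the deduplicated OpinionKB
#'
#' Collapses polarity-tagged quadruples into a knowledge base keyed by
#' case-insensitive (effective, affected, relation). Redundant quadruples are
#' discarded; when the same key was tagged with conflicting polarities, the
#' higher-confidence assignment wins and exact confidence ties drop the key
#' entirely (reported in the `"dropped"` attribute). `support` records how
#' many occurrences carried the kept polarity.
#'
#' @param quads Quadruples with non-`NA` `polarity` (and a `confidence`
#'   column; missing confidences count as 1).
#' @return A tibble of class `opinion_kb`: `effective`, `affected`,
#'   `relation`, `polarity`, `confidence`, `support`.
#' @export
build_opinion_kb <- function(quads) {
  if (nrow(quads) > 0 && any(is.na(quads$polarity))) {
    stop("all quadruples must be polarity-tagged before entering the OpinionKB",
      call. = FALSE
    )
  }
  if (nrow(quads) == 0) {
    out <- tibble::tibble(
      effective = character(), affected = character(), relation = character(),
      polarity = character(), confidence = numeric(), support = integer()
    )
    return(structure(out,
      dropped = out[0, c("effective", "affected", "relation")],
      class = c("opinion_kb", class(out))
    ))
  }
  conf <- if ("confidence" %in% names(quads)) {
    dplyr::coalesce(quads$confidence, 1)
  } else {
    rep(1, nrow(quads))
  }
  tab <- tibble::tibble(
    effective = tolower(quads$effective),
    affected = tolower(quads$affected),
    relation = tolower(quads$relation),
    polarity = quads$polarity,
    confidence = conf
  ) |>
    dplyr::summarise(
      confidence = max(.data$confidence),
      support = dplyr::n(),
      .by = c("effective", "affected", "relation", "polarity")
    )
  resolved <- tab |>
    dplyr::group_by(.data$effective, .data$affected, .data$relation) |>
    dplyr::filter(.data$confidence == max(.data$confidence)) |>
    dplyr::ungroup()
  dup <- resolved |>
    dplyr::count(.data$effective, .data$affected, .data$relation) |>
    dplyr::filter(.data$n > 1)
  dropped <- dup[, c("effective", "affected", "relation")]
  out <- resolved |>
    dplyr::anti_join(dropped, by = c("effective", "affected", "relation")) |>
    dplyr::arrange(.data$effective, .data$affected, .data$relation)
  structure(out, dropped = dropped, class = c("opinion_kb", class(out)))
}

entity_sem_type <- function(term, lexicon) {
  term <- tolower(term)
  j <- match(term, lexicon$term)
  if (is.na(j)) { # back off to the phrase head
    head_w <- stringr::str_extract(term, "\\S+$")
    j <- match(head_w, lexicon$term)
  }
  if (is.na(j)) NA_character_ else lexicon$sem_type[j]
}

type_to_group <- function(types, lexicon) {
  map <- unique(tibble::tibble(
    sem_type = lexicon$sem_type, sem_group = lexicon$sem_group
  ))
  map$sem_group[match(types, map$sem_type)]
}

#' Mine frequent semantic-type and semantic-group polarity patterns
#'
#' Type-level patterns substitute both entities of each OpinionKB entry by
#' their semantic types and keep the combinations supported by strictly more
#' than `threshold` KB entries; group-level patterns are derived from the
#' retained type patterns by substituting types with groups, re-applying the
#' same support threshold. The relation verb lemma is kept at both levels.
#' A pattern whose instances disagree on polarity keeps the majority
#' polarity; exact ties are dropped.
#'
#' @param kb An [build_opinion_kb()] result.
#' @param lexicon A [semantic_lexicon()] used for the substitutions.
#' @param threshold Strict support bound (default 3).
#' @return A tibble of class `opinion_patterns`: `level` (type/group),
#'   `effective_code`, `affected_code`, `relation`, `polarity`, `support`.
#' @export
mine_patterns <- function(kb, lexicon, threshold = 3) {
  empty <- structure(
    tibble::tibble(
      level = character(), effective_code = character(),
      affected_code = character(), relation = character(),
      polarity = character(), support = integer()
    ),
    class = c("opinion_patterns", "tbl_df", "tbl", "data.frame")
  )
  if (nrow(kb) == 0) {
    return(empty)
  }
  typed <- tibble::as_tibble(kb) |>
    dplyr::mutate(
      effective_code = purrr::map_chr(.data$effective, entity_sem_type,
        lexicon = lexicon
      ),
      affected_code = purrr::map_chr(.data$affected, entity_sem_type,
        lexicon = lexicon
      )
    ) |>
    dplyr::filter(!is.na(.data$effective_code), !is.na(.data$affected_code))
  if (nrow(typed) == 0) {
    return(empty)
  }
  majority <- function(df) {
    df |>
      dplyr::summarise(support = dplyr::n(),
        .by = c("effective_code", "affected_code", "relation", "polarity")
      ) |>
      dplyr::group_by(.data$effective_code, .data$affected_code, .data$relation) |>
      dplyr::filter(
        .data$support == max(.data$support),
        # exact polarity tie (two rows at the max) -> drop the pattern
        sum(.data$support == max(.data$support)) == 1
      ) |>
      dplyr::ungroup()
  }
  type_pat <- majority(typed) |>
    dplyr::filter(.data$support > threshold) |>
    dplyr::mutate(level = "type")
  if (nrow(type_pat) == 0) {
    return(empty)
  }
  group_src <- type_pat |>
    dplyr::mutate(
      effective_code = type_to_group(.data$effective_code, lexicon),
      affected_code = type_to_group(.data$affected_code, lexicon)
    ) |>
    # expand back to entry granularity so group support counts KB entries
    tidyr::uncount(.data$support)
  group_pat <- majority(group_src) |>
    dplyr::filter(.data$support > threshold) |>
    dplyr::mutate(level = "group")
  out <- dplyr::bind_rows(type_pat, group_pat) |>
    dplyr::select(
      "level", "effective_code", "affected_code", "relation",
      "polarity", "support"
    ) |>
    dplyr::arrange(.data$level, dplyr::desc(.data$support))
  class(out) <- c("opinion_patterns", class(out))
  out
}

#' Classify new quadruples with the OpinionKB and pattern backoff
#'
#' Three-step backoff: (1) exact knowledge-base key lookup; (2) substitute
#' both entities by their semantic types and search the type-level patterns;
#' (3) substitute by semantic groups and search the group-level patterns.
#' The first hit returns its polarity; quadruples matching nothing stay
#' `untagged`, as do quadruples whose entities the lexicon cannot type
#' (with a warning).
#'
#' @param quads Polarity-null quadruples (need `effective`, `affected`,
#'   `relation`).
#' @param kb An `opinion_kb`.
#' @param patterns Patterns from [mine_patterns()].
#' @param lexicon A [semantic_lexicon()].
#' @return `quads` with `polarity` (`positive`/`negative`/`untagged`) and
#'   `step` (`kb`/`type`/`group`/`none`) columns.
#' @export
classify_quadruples <- function(quads, kb, patterns, lexicon) {
  if (nrow(quads) == 0) {
    quads$polarity <- character()
    quads$step <- character()
    return(quads)
  }
  kb_key <- paste(kb$effective, kb$affected, kb$relation, sep = "\r")
  tpat <- patterns[patterns$level == "type", , drop = FALSE]
  gpat <- patterns[patterns$level == "group", , drop = FALSE]
  t_key <- paste(tpat$effective_code, tpat$affected_code, tpat$relation, sep = "\r")
  g_key <- paste(gpat$effective_code, gpat$affected_code, gpat$relation, sep = "\r")
  res <- purrr::pmap(
    quads[, c("effective", "affected", "relation")],
    function(effective, affected, relation) {
      e <- tolower(effective); a <- tolower(affected); r <- tolower(relation)
      j <- match(paste(e, a, r, sep = "\r"), kb_key)
      if (!is.na(j)) {
        return(list(polarity = kb$polarity[j], step = "kb"))
      }
      te <- entity_sem_type(e, lexicon)
      ta <- entity_sem_type(a, lexicon)
      if (is.na(te) || is.na(ta)) {
        warning("cannot type entities of quadruple (", e, ", ", a, ", ", r,
          "); left untagged",
          call. = FALSE
        )
        return(list(polarity = "untagged", step = "none"))
      }
      j <- match(paste(te, ta, r, sep = "\r"), t_key)
      if (!is.na(j)) {
        return(list(polarity = tpat$polarity[j], step = "type"))
      }
      ge <- type_to_group(te, lexicon)
      ga <- type_to_group(ta, lexicon)
      j <- match(paste(ge, ga, r, sep = "\r"), g_key)
      if (!is.na(j)) {
        return(list(polarity = gpat$polarity[j], step = "group"))
      }
      list(polarity = "untagged", step = "none")
    }
  )
  quads$polarity <- purrr::map_chr(res, "polarity")
  quads$step <- purrr::map_chr(res, "step")
  quads
}

#' @export
tidy.opinion_kb <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.opinion_kb <- function(x, ...) {
  tibble::tibble(
    n_quadruples = nrow(x),
    n_positive = sum(x$polarity == "positive"),
    n_negative = sum(x$polarity == "negative"),
    n_drugs = dplyr::n_distinct(x$effective),
    n_dropped_conflicts = nrow(attr(x, "dropped") %||% x[0, ]),
    mean_support = if (nrow(x) > 0) mean(x$support) else NA_real_
  )
}

#' @export
glance.opinion_patterns <- function(x, ...) {
  tibble::tibble(
    n_type_patterns = sum(x$level == "type"),
    n_group_patterns = sum(x$level == "group"),
    max_support = if (nrow(x) > 0) max(x$support) else NA_integer_
  )
}

#' Plot OpinionKB polarity composition
#'
#' Stacked counts of positive and negative quadruples per effective entity.
#'
#' @param object An `opinion_kb`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.opinion_kb <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(
      y = stats::reorder(.data$effective, .data$effective, length),
      fill = .data$polarity
    )
  ) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      y = "effective entity (drug)", x = "quadruples",
      title = "OpinionKB composition"
    )
}
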