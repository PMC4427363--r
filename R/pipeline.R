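#' Tag raw texts with the semantic lexicon
#'
#' Tokenizes free-text lines (e.g. the mixed-topic background opinions) and
#' matches entity mentions, for semantic-group counting.
#'
#' @param texts Character vector.
#' @param lexicon A [semantic_lexicon()].
#' @param tagger A tagger.
#' @return A mentions tibble (role column absent: no group selection yet).
#' @export
tag_texts <- function(texts, lexicon, tagger = default_tagger()) {
  uniq <- unique(texts)
  tok_cache <- purrr::map(uniq, tokenize_text, tagger = tagger)
  units <- tibble::tibble(
    unit_id = paste0("txt", seq_along(texts)),
    review_id = NA_integer_,
    field = "background",
    tokens = tok_cache[match(texts, uniq)]
  )
  tag_entities(units, lexicon)
}

#' Default pipeline parameters
#'
#' All tunables of the resource-construction pipeline in one place:
#' `alpha`/`theta` for SGF-IOF group selection, `beta` for the phrase
#' minimum-support bound, `freq_threshold` for the cascade frequency filter,
#' `pattern_threshold` for pattern mining, `cd_min` for the confidence-degree
#' rule, `rating_pos`/`rating_neg` comment-field rating cutoffs, `any_drug`
#' CompIndi matching, and the candidate `window`.
#'
#' @param ... Overrides of the defaults.
#' @return A named list.
#' @export
pipeline_params <- function(...) {
  params <- list(
    alpha = 0.4, theta = 0.084, beta = 3, freq_threshold = 3,
    pattern_threshold = 3, cd_min = 3, rating_pos = 4, rating_neg = 2,
    any_drug = FALSE, window = Inf,
    conditional_markers = c("if", "unless", "would")
  )
  utils::modifyList(params, list(...))
}

#' Build the indirect-opinion resources from structured reviews
#'
#' Runs the full construction pipeline: preprocessing, SGF-IOF affected-group
#' selection against the mixed-topic background, entity tagging, complete and
#' incomplete opinion extraction, polarity detection, OpinionKB construction,
#' pattern mining and corpus annotation.
#'
#' @param reviews Reviews tibble ([read_reviews()] or the simulator).
#' @param dkb A [domain_kb()].
#' @param store A [triple_store()].
#' @param lexicon A [semantic_lexicon()].
#' @param background Character vector of mixed-topic opinion lines used as
#'   the SGF-IOF background; `NULL` skips group selection and treats every
#'   non-drug group as affected.
#' @param params [pipeline_params()].
#' @param tagger A tagger.
#' @return A list of class `opinion_resources`: `units`, `mentions`,
#'   `weights` (SGF-IOF table, `NULL` without background),
#'   `affected_groups`, `quadruples` (polarity-tagged), `kb`, `patterns`,
#'   `corpus`, and the extraction `log`.
#' @export
build_opinion_resources <- function(reviews, dkb, store, lexicon,
                                    background = NULL,
                                    params = pipeline_params(),
                                    tagger = default_tagger()) {
  units <- prep_reviews(reviews, tagger, lexicon,
    conditional_markers = params$conditional_markers
  )
  pre_mentions <- tag_entities(units, lexicon)
  if (!is.null(background)) {
    dom_counts <- count_sem_groups(pre_mentions)
    bg_counts <- count_sem_groups(tag_texts(background, lexicon, tagger))
    weights <- compute_sgf_iof(dom_counts, bg_counts, alpha = params$alpha)
    groups <- select_affected_groups(weights, theta = params$theta)
  } else {
    weights <- NULL
    drug_groups <- unique(lexicon$sem_group[
      lexicon$sem_type %in% attr(lexicon, "drug_types")
    ])
    groups <- setdiff(unique(lexicon$sem_group), drug_groups)
  }
  mentions <- tag_entities(units, lexicon, affected_groups = groups)
  quads <- extract_opinions(units, mentions, dkb, store, lexicon,
    beta = params$beta, freq_threshold = params$freq_threshold,
    any_drug = params$any_drug, window = params$window
  )
  log <- attr(quads, "log")
  tagged <- assign_polarities(quads, units, dkb,
    cd_min = params$cd_min,
    rating_pos = params$rating_pos, rating_neg = params$rating_neg
  )
  final <- tagged[!is.na(tagged$polarity), , drop = FALSE]
  kb <- build_opinion_kb(final)
  patterns <- mine_patterns(kb, lexicon, threshold = params$pattern_threshold)
  corpus <- annotate_opinions(final, units, mentions)
  structure(
    list(
      units = units, mentions = mentions, weights = weights,
      affected_groups = groups, quadruples = tagged, kb = kb,
      patterns = patterns, corpus = corpus, log = log
    ),
    class = "opinion_resources"
  )
}

#' @export
print.opinion_resources <- function(x, ...) {
  cat("Indirect-opinion resources\n")
  cat("  units:            ", nrow(x$units), "\n")
  cat("  affected groups:  ", paste(x$affected_groups, collapse = ", "), "\n")
  cat("  quadruples:       ", nrow(x$quadruples),
    " (", sum(!is.na(x$quadruples$polarity)), " polarity-tagged)\n",
    sep = ""
  )
  cat("  OpinionKB entries:", nrow(x$kb), "\n")
  cat("  patterns:         ", nrow(x$patterns), "\n")
  cat("  corpus records:   ", nrow(x$corpus), "\n")
  invisible(x)
}

#' @export
glance.opinion_resources <- function(x, ...) {
  tibble::tibble(
    n_units = nrow(x$units),
    n_quadruples = nrow(x$quadruples),
    n_tagged = sum(!is.na(x$quadruples$polarity)),
    n_kb = nrow(x$kb),
    n_patterns = nrow(x$patterns),
    n_corpus = nrow(x$corpus)
  )
}

#' Classify the polarity of new review sentences with an OpinionKB
#'
#' Test-time use of the constructed resources: extracts quadruples from new
#' reviews with the same machinery as resource construction, except that the
#' incomplete-opinion filtering phase is skipped (every candidate sentence is
#' assumed to be an indirect opinion), then classifies each quadruple by the
#' three-step KB/pattern backoff.
#'
#' @param reviews New reviews tibble.
#' @param kb An `opinion_kb`.
#' @param patterns Patterns from [mine_patterns()].
#' @param lexicon A [semantic_lexicon()].
#' @param affected_groups Affected-group selection to reuse.
#' @param params [pipeline_params()].
#' @param tagger A tagger.
#' @return Quadruples with `polarity`
#'   (`positive`/`negative`/`untagged`) and backoff `step`.
#' @export
classify_reviews <- function(reviews, kb, patterns, lexicon,
                             affected_groups, params = pipeline_params(),
                             tagger = default_tagger()) {
  units <- prep_reviews(reviews, tagger, lexicon,
    conditional_markers = params$conditional_markers
  )
  mentions <- tag_entities(units, lexicon, affected_groups = affected_groups)
  complete <- extract_complete_opinions(units, mentions)
  cands <- propose_incomplete_candidates(units, mentions, window = params$window)
  incomplete <- if (nrow(cands) > 0) {
    cands$stage <- "unfiltered"
    cands$accepted <- TRUE
    cands$resolved_subject <- tolower(cands$drug)
    cascade_to_quadruples(cands)
  } else {
    empty_quadruples()
  }
  # phrases, likewise unfiltered: every descriptor/shifter phrase is taken
  phr <- extract_phrase_opinions(units, mentions,
    dkb = domain_kb(character(), character(), character(), character()),
    accept_all = TRUE
  )
  quads <- dplyr::bind_rows(complete, incomplete, phr$quadruples)
  classify_quadruples(quads, kb, patterns, lexicon)
}
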