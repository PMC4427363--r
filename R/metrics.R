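#' Precision, recall and F-measure from confusion counts
#'
#' Precision is the percentage of classified instances that are correct,
#' recall the percentage of all instances that are correctly classified, and
#' the F-measure their harmonic mean. Values are kept exact internally and
#' reported as percentages; zero denominators make the affected metric
#' undefined (`NA`), never 0 by convention.
#'
#' @param n_correct Correctly classified instances.
#' @param n_classified Total classified instances.
#' @param n_total Total instances (`NA` allowed when recall is not of
#'   interest).
#' @return A one-row tibble of class `okb_metrics`: the counts plus
#'   `precision`, `recall`, `f_measure` in percent.
#' @export
compute_metrics <- function(n_correct, n_classified, n_total = NA_integer_) {
  stopifnot(n_correct >= 0, n_classified >= 0)
  if (n_correct > n_classified) {
    stop("n_correct cannot exceed n_classified", call. = FALSE)
  }
  if (!is.na(n_total) && n_classified >= 0 && n_correct > n_total) {
    stop("n_correct cannot exceed n_total", call. = FALSE)
  }
  precision <- if (n_classified > 0) 100 * n_correct / n_classified else NA_real_
  recall <- if (!is.na(n_total) && n_total > 0) {
    100 * n_correct / n_total
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    n_correct = n_correct, n_classified = n_classified, n_total = n_total,
    precision = precision, recall = recall,
    f_measure = f_measure(precision, recall)
  )
  class(out) <- c("okb_metrics", class(out))
  out
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Percentages.
#' @return `2 * precision * recall / (precision + recall)`; `NA` when either
#'   input is `NA` or both are zero.
#' @export
f_measure <- function(precision, recall) {
  ifelse(
    is.na(precision) | is.na(recall) | (precision + recall) == 0,
    NA_real_,
    2 * precision * recall / (precision + recall)
  )
}

#' @export
print.okb_metrics <- function(x, ...) {
  y <- tibble::as_tibble(x)
  y$precision <- round(y$precision, 2)
  y$recall <- round(y$recall, 2)
  y$f_measure <- round(y$f_measure, 2)
  print(y, ...)
  invisible(x)
}

#' Evaluate predicted quadruples against a gold standard
#'
#' Matching is binary quadruple-key equality at lemma level within a review:
#' `(review_id, effective, affected, relation)`, case-insensitive, with
#' multiplicity (two identical gold keys need two predictions). Reported
#' blocks: extraction metrics for complete, incomplete and all opinions;
#' polarity precision among correctly extracted opinions; and overall
#' precision (correct extraction AND correct polarity).
#'
#' @param predictions,gold Quadruple tibbles with `review_id`, `effective`,
#'   `affected`, `relation`, `completeness`, `polarity`.
#' @return A tibble of class `opinion_eval`: one row per block (`module`),
#'   with the [compute_metrics()] columns.
#' @export
evaluate_run <- function(predictions, gold) {
  orphans <- setdiff(unique(predictions$review_id), unique(gold$review_id))
  if (length(orphans) > 0 && nrow(gold) > 0) {
    stop("predictions reference unknown review ids: ",
      paste(utils::head(orphans, 10), collapse = ", "),
      call. = FALSE
    )
  }
  keyed <- function(df) {
    df |>
      dplyr::mutate(
        .key = paste(.data$review_id, tolower(.data$effective),
          tolower(.data$affected), tolower(.data$relation),
          sep = "\r"
        )
      ) |>
      dplyr::mutate(.occ = dplyr::row_number(), .by = ".key")
  }
  p <- keyed(tibble::as_tibble(predictions))
  g <- keyed(tibble::as_tibble(gold))
  matched <- dplyr::inner_join(
    p[, c(".key", ".occ", "polarity")],
    g[, c(".key", ".occ", "completeness", "polarity")],
    by = c(".key", ".occ"), suffix = c("_pred", "_gold")
  )
  block <- function(module, pred_n, gold_df, matched_df) {
    m <- compute_metrics(nrow(matched_df), pred_n, nrow(gold_df))
    dplyr::bind_cols(tibble::tibble(module = module), tibble::as_tibble(m))
  }
  out <- dplyr::bind_rows(
    block(
      "extraction_complete",
      sum(p$completeness == "complete"),
      g[g$completeness == "complete", ],
      matched[matched$completeness == "complete", ]
    ),
    block(
      "extraction_incomplete",
      sum(p$completeness == "incomplete"),
      g[g$completeness == "incomplete", ],
      matched[matched$completeness == "incomplete", ]
    ),
    block("extraction_overall", nrow(p), g, matched),
    {
      pol_ok <- matched$polarity_pred == matched$polarity_gold
      m <- compute_metrics(sum(pol_ok, na.rm = TRUE), nrow(matched))
      dplyr::bind_cols(
        tibble::tibble(module = "polarity"), tibble::as_tibble(m)
      )
    },
    {
      pol_ok <- matched$polarity_pred == matched$polarity_gold
      m <- compute_metrics(sum(pol_ok, na.rm = TRUE), nrow(p), nrow(g))
      dplyr::bind_cols(
        tibble::tibble(module = "overall"), tibble::as_tibble(m)
      )
    }
  )
  class(out) <- c("opinion_eval", class(out))
  out
}

#' @export
glance.opinion_eval <- function(x, ...) {
  ov <- x[x$module == "overall", ]
  tibble::tibble(
    precision = ov$precision, recall = ov$recall, f_measure = ov$f_measure
  )
}

#' Plot evaluation metrics per module
#'
#' @param object An `opinion_eval` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.opinion_eval <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("precision", "recall", "f_measure"),
      names_to = "metric", values_to = "value"
    ) |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$module, y = .data$value, fill = .data$metric)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "percent", title = "Evaluation metrics")
}
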