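#' SGF-IOF semantic-group weighting
#'
#' Scores how characteristic each semantic group is of the target opinion
#' domain relative to a mixed-topic background. For group `sg`, with
#' `n_sg_d` occurrences in the domain subset `d`, `sum_nk_d` total group
#' occurrences in `d`, `n_sg` occurrences in the whole opinion set and
#' `sum_nk` total occurrences in the whole set:
#'
#' `weight = (n_sg_d / sum_nk_d) * log(alpha * sum_nk / n_sg)`
#'
#' with natural log. `alpha` balances the group-frequency term against the
#' inverse-opinion-frequency term. Groups absent from the domain subset get
#' weight 0; negative weights are possible and simply fall below any positive
#' threshold. Counting is done over group codes after each entity mention is
#' replaced by its group, so the entity name itself carries no weight.
#'
#' @param domain_counts Tibble/data frame with columns `sem_group`, `n`
#'   (counts in the domain opinion subset `d`).
#' @param background_counts Same layout, counts in the whole opinion set
#'   (background including the domain; if the domain rows are not contained in
#'   it the two are summed).
#' @param alpha Positive weighting constant (default 0.4).
#' @param include_domain Set `FALSE` if `background_counts` already includes
#'   the domain counts; by default they are added.
#' @return A tibble of class `sgf_iof`: `sem_group`, `n_sg_d`, `sum_nk_d`,
#'   `n_sg`, `sum_nk`, `alpha`, `weight`, ordered by decreasing weight.
#' @export
compute_sgf_iof <- function(domain_counts, background_counts,
                            alpha = 0.4, include_domain = TRUE) {
  stopifnot(alpha > 0)
  dom <- normalize_counts(domain_counts)
  bg <- normalize_counts(background_counts)
  whole <- dplyr::bind_rows(dom, bg) |>
    dplyr::summarise(n_sg = sum(.data$n), .by = "sem_group")
  if (!include_domain) {
    whole <- normalize_counts(background_counts) |>
      dplyr::rename(n_sg = "n")
  }
  sum_nk_d <- sum(dom$n)
  if (sum_nk_d == 0) {
    stop("empty domain opinion set: no semantic group occurrences", call. = FALSE)
  }
  sum_nk <- sum(whole$n_sg)
  tab <- whole |>
    dplyr::left_join(dplyr::rename(dom, n_sg_d = "n"), by = "sem_group") |>
    dplyr::mutate(n_sg_d = dplyr::coalesce(.data$n_sg_d, 0L))
  if (any(tab$n_sg_d > 0 & tab$n_sg == 0)) {
    stop("inconsistent counts: group present in domain but absent from whole set",
      call. = FALSE
    )
  }
  if (any(tab$n_sg_d > tab$n_sg)) {
    stop("inconsistent counts: domain count exceeds whole-set count", call. = FALSE)
  }
  out <- tab |>
    dplyr::mutate(
      sum_nk_d = sum_nk_d,
      sum_nk = sum_nk,
      alpha = alpha,
      weight = ifelse(
        .data$n_sg_d == 0, 0,
        (.data$n_sg_d / sum_nk_d) * log(alpha * sum_nk / .data$n_sg)
      )
    ) |>
    dplyr::select(
      "sem_group", "n_sg_d", "sum_nk_d", "n_sg", "sum_nk", "alpha", "weight"
    ) |>
    dplyr::arrange(dplyr::desc(.data$weight))
  class(out) <- c("sgf_iof", class(out))
  out
}

normalize_counts <- function(counts) {
  stopifnot(all(c("sem_group", "n") %in% names(counts)))
  counts <- tibble::as_tibble(counts)[, c("sem_group", "n")]
  if (any(counts$n < 0) || any(counts$n != round(counts$n))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dplyr::summarise(counts, n = sum(.data$n), .by = "sem_group")
}

#' Count semantic-group occurrences in mentions
#'
#' Helper that turns a mentions tibble (or any table with a `sem_group`
#' column) into the group-count layout [compute_sgf_iof()] expects.
#'
#' @param mentions Tibble with a `sem_group` column.
#' @return Tibble with `sem_group`, `n`.
#' @export
count_sem_groups <- function(mentions) {
  if (nrow(mentions) == 0) {
    return(tibble::tibble(sem_group = character(), n = integer()))
  }
  dplyr::count(tibble::as_tibble(mentions), .data$sem_group, name = "n")
}

#' Select affected-entity semantic groups
#'
#' Keeps every group whose SGF-IOF weight is at least `theta`. An empty
#' selection (all weights below the threshold) is legal but leaves the
#' pipeline with no affected entities, so it is flagged with a warning.
#'
#' @param weights An `sgf_iof` tibble from [compute_sgf_iof()].
#' @param theta Selection threshold (default 0.084).
#' @return Character vector of selected group codes.
#' @export
select_affected_groups <- function(weights, theta = 0.084) {
  sel <- weights$sem_group[weights$weight >= theta]
  if (length(sel) == 0) {
    warning(
      "no semantic group reaches theta = ", theta,
      "; no affected entities will be found",
      call. = FALSE
    )
  }
  sel
}

#' Plot SGF-IOF group weights
#'
#' Bar chart of group weights with the selection threshold drawn as a dashed
#' line.
#'
#' @param object An `sgf_iof` tibble.
#' @param theta Threshold to draw.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.sgf_iof <- function(object, theta = 0.084, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(
      x = stats::reorder(.data$sem_group, .data$weight),
      y = .data$weight,
      fill = .data$weight >= theta
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = theta, linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = "semantic group", y = "SGF-IOF weight",
      title = "Affected-group selection",
      subtitle = paste0("dashed line: theta = ", theta)
    )
}
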