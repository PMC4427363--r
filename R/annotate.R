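#' Annotate an extracted opinion in its sentence
#'
#' Produces the corpus record for one tagged quadruple: the original unit
#' text, an inline bracket-annotated rendering, the structured tags, the
#' opinion type (complete/incomplete) and polarity. In the inline rendering
#' entity spans are wrapped as `[surface/role/type/group]`, the main verb as
#' `[surface/main-verb]` and valence shifters as `[surface/negation]` /
#' `[surface/quantifier]`; trailing sentence punctuation is dropped. The
#' bracket string is a derived rendering; the structured tags are the
#' canonical storage.
#'
#' @param quads Polarity-tagged quadruples.
#' @param units Units tibble the quadruples came from.
#' @param mentions Mentions tibble ([tag_entities()]).
#' @return A corpus tibble: identifiers, `text`, `inline`, `effective`,
#'   `affected`, `relation`, `completeness`, `polarity` and a `tags`
#'   list-column.
#' @export
annotate_opinions <- function(quads, units, mentions) {
  if (nrow(quads) == 0) {
    return(empty_corpus())
  }
  if (any(is.na(quads$polarity))) {
    stop("quadruples must be polarity-tagged before annotation", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(quads)), function(i) {
    q <- quads[i, ]
    u <- units[units$unit_id == q$unit_id, , drop = FALSE]
    if (nrow(u) != 1) {
      stop("unit ", q$unit_id, " not found for quadruple ", i, call. = FALSE)
    }
    tokens <- u$tokens[[1]]
    m <- mentions[mentions$unit_id == q$unit_id, , drop = FALSE]
    tags <- list()
    add_tag <- function(surface, tag, start, end, sem_type = NULL,
                        sem_group = NULL) {
      t <- list(
        surface = surface, tag = tag,
        start = as.integer(start), end = as.integer(end)
      )
      if (!is.null(sem_type)) {
        t$sem_type <- sem_type
        t$sem_group <- sem_group
      }
      tags[[length(tags) + 1L]] <<- t
    }
    eff <- m[m$role == "effective" & m$lemma == tolower(q$effective), ,
      drop = FALSE
    ]
    if (nrow(eff) > 0) {
      add_tag(
        eff$surface[1], "effective-entity", eff$start[1], eff$end[1],
        eff$sem_type[1], eff$sem_group[1]
      )
    }
    aff <- m[m$role == "affected" &
      (m$lemma == tolower(q$affected) |
        endsWith(tolower(q$affected), paste0(" ", m$lemma))), ,
    drop = FALSE
    ]
    if (nrow(aff) == 0) {
      stop("affected span '", q$affected, "' not locatable in unit ",
        q$unit_id,
        call. = FALSE
      )
    }
    add_tag(
      aff$surface[1], "affected-entity", aff$start[1], aff$end[1],
      aff$sem_type[1], aff$sem_group[1]
    )
    mv <- extract_main_verbs(tokens)
    if (nrow(mv) > 0 && q$completeness == "complete") {
      add_tag(
        tokens$surface[mv$index], "main-verb",
        tokens$start[mv$index], tokens$end[mv$index]
      )
    } else if (nrow(mv) > 0 && q$relation != "cause") {
      add_tag(
        tokens$surface[mv$index], "main-verb",
        tokens$start[mv$index], tokens$end[mv$index]
      )
    }
    negs <- which(tokens$pos == "PART" &
      tokens$lemma %in% c("not", "no", "never", "n't", "none"))
    for (k in negs) {
      add_tag(tokens$surface[k], "negation", tokens$start[k], tokens$end[k])
    }
    quants <- which(tokens$pos == "QUANT")
    for (k in quants) {
      add_tag(tokens$surface[k], "quantifier", tokens$start[k], tokens$end[k])
    }
    tibble::tibble(
      review_id = q$review_id, unit_id = q$unit_id, field = q$field,
      text = u$text, inline = render_inline(u$text, tags),
      effective = q$effective, affected = q$affected, relation = q$relation,
      completeness = q$completeness, polarity = q$polarity,
      tags = list(tags)
    )
  })
  dplyr::bind_rows(rows)
}

empty_corpus <- function() {
  tibble::tibble(
    review_id = integer(), unit_id = character(), field = character(),
    text = character(), inline = character(), effective = character(),
    affected = character(), relation = character(), completeness = character(),
    polarity = character(), tags = list()
  )
}

render_inline <- function(text, tags) {
  ord <- order(purrr::map_int(tags, "start"), decreasing = TRUE)
  out <- stringr::str_remove(text, "\\s*[.!?]+\\s*$")
  for (t in tags[ord]) {
    if (t$start >= nchar(out)) next # tag fell in stripped punctuation
    label <- if (!is.null(t$sem_type)) {
      paste(t$surface, t$tag, t$sem_type, t$sem_group, sep = "/")
    } else {
      paste(t$surface, t$tag, sep = "/")
    }
    out <- paste0(
      substr(out, 1, t$start), "[", label, "]",
      substr(out, t$end + 1, nchar(out))
    )
  }
  out
}

#' Parse an inline bracket annotation
#'
#' Inverse of the inline rendering: recovers the plain text (brackets
#' removed) and the tag list.
#'
#' @param inline An inline-annotated string.
#' @return List with `text` and `tags` (same layout as [annotate_opinions()]
#'   tags, with offsets into the recovered plain text).
#' @export
parse_inline <- function(inline) {
  tags <- list()
  out <- inline
  repeat {
    m <- stringr::str_locate(out, "\\[[^\\[\\]]+\\]")
    if (any(is.na(m))) break
    inner <- substr(out, m[1] + 1, m[2] - 1)
    parts <- stringr::str_split(inner, "/")[[1]]
    # the surface itself may contain no "/": tag fields come from the tail
    if (length(parts) >= 4 &&
      parts[length(parts) - 2] %in% c("effective-entity", "affected-entity")) {
      k <- length(parts)
      t <- list(
        surface = paste(parts[1:(k - 3)], collapse = "/"),
        tag = parts[k - 2],
        sem_type = parts[k - 1], sem_group = parts[k]
      )
    } else {
      k <- length(parts)
      t <- list(
        surface = paste(parts[1:(k - 1)], collapse = "/"),
        tag = parts[k]
      )
    }
    t$start <- as.integer(m[1] - 1L)
    t$end <- as.integer(m[1] - 1L + nchar(t$surface))
    tags[[length(tags) + 1L]] <- t
    out <- paste0(
      substr(out, 1, m[1] - 1), t$surface,
      substr(out, m[2] + 1, nchar(out))
    )
  }
  list(text = out, tags = tags)
}

#' Write / read the annotated corpus
#'
#' Line-delimited JSON records, one per accepted indirect opinion, carrying
#' text, inline rendering, quadruple fields, opinion type, polarity,
#' provenance and the structured tags. `read_corpus(write_corpus(x))`
#' round-trips field for field.
#'
#' @param corpus A corpus tibble from [annotate_opinions()].
#' @param path File path.
#' @return [read_corpus()] returns the corpus tibble.
#' @export
write_corpus <- function(corpus, path) {
  write_jsonl(corpus, path)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  out <- read_jsonl(path, c(
    review_id = "integer", unit_id = "character", field = "character",
    text = "character", inline = "character", effective = "character",
    affected = "character", relation = "character",
    completeness = "character", polarity = "character", tags = "list"
  ))
  # rebuild tag records with stable types
  out$tags <- purrr::map(out$tags, function(tl) {
    purrr::map(tl, function(t) {
      t$start <- as.integer(t$start)
      t$end <- as.integer(t$end)
      keys <- c("surface", "tag", "start", "end", "sem_type", "sem_group")
      t[intersect(keys, names(t))]
    })
  })
  out
}
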