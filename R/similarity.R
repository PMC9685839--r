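## Weighted extent/intent set-overlap similarity and ranked retrieval.

check_params <- function(alpha, beta) {
  if (!is.numeric(alpha) || !is.numeric(beta) || length(alpha) != 1 ||
      length(beta) != 1 || is.na(alpha) || is.na(beta) || alpha < 0 || beta < 0 ||
      alpha + beta <= 0) {
    stop_validation("alpha and beta must be non-negative with alpha + beta > 0")
  }
}

overlap_term <- function(s1, s2) {
  m <- max(length(s1), length(s2))
  if (m == 0) return(0)   # both sets empty: the term contributes nothing
  length(intersect(s1, s2)) / m
}

#' Weighted similarity between two concepts
#'
#' The similarity between concepts (A1, B1) and (A2, B2) is
#' \deqn{Sim = \alpha\,\frac{|A_1 \cap A_2|}{\max(|A_1|,|A_2|)} +
#'             \beta\,\frac{|B_1 \cap B_2|}{\max(|B_1|,|B_2|)}}
#' a weighted sum of the extent (shared patients) and intent (shared
#' attributes) overlap ratios. With `alpha = beta = 0.5` objects and
#' attributes are weighted equally; case retrieval for a new patient — who is
#' not yet in the knowledge base, so has no extent — uses `alpha = 0,
#' beta = 1`. A term whose two sets are both empty contributes 0.
#'
#' @param c1,c2 [formal_concept()]s (or lists with `extent`/`intent` fields)
#'   over the same context universes.
#' @param alpha,beta non-negative weights on the extent and intent terms;
#'   `alpha + beta` must be positive.
#' @return numeric score in `[0, alpha + beta]`, symmetric in its arguments.
#' @examples
#' a <- formal_concept(c("P2", "P3"), c("Age_M", "Lym_H"))
#' concept_similarity(a, a)                       # 1 (alpha = beta = 0.5)
#' b <- formal_concept("P1", c("Age_H", "Lym_L", "CEA_H"))
#' concept_similarity(a, b, alpha = 0, beta = 1)  # 0: disjoint intents
#' @export
concept_similarity <- function(c1, c2, alpha = 0.5, beta = 0.5) {
  check_params(alpha, beta)
  alpha * overlap_term(c1$extent, c2$extent) +
    beta * overlap_term(c1$intent, c2$intent)
}

#' Build a retrieval query from a set of attributes
#'
#' A new patient is represented as a concept-shaped query with the given
#' attributes as intent and an empty extent (the patient is not in the
#' knowledge base). Such a query is meaningful wherever the extent term
#' contributes 0, i.e. with `alpha = 0` — the default retrieval setting.
#'
#' @param attributes nonempty character vector of attribute names; spelling
#'   variants are normalized (see [normalize_attributes()]).
#' @param context the [formal_context()] whose attribute universe the query
#'   is checked against.
#' @return a [formal_concept()] with empty extent, id `"query"`.
#' @export
query_from_attributes <- function(attributes, context) {
  if (length(attributes) == 0) stop_validation("query attribute set is empty")
  att <- normalize_attributes(attributes, context$attributes)
  att <- context$attributes[sort(match(unique(att), context$attributes))]
  formal_concept(character(0), att, id = "query")
}

#' Retrieve concepts similar to a query
#'
#' Scores every concept of the knowledge base against the query with
#' [concept_similarity()] and returns the `top_k` ranked results. Defaults
#' follow the case-retrieval setting (`alpha = 0`, `beta = 1`): a concept
#' whose intent equals the query's attribute set scores exactly 1. Concepts
#' with an empty extent (the lattice bottom when no patient has all
#' attributes) are excluded by default, since their full intent would match
#' any query spuriously.
#'
#' Ties are broken deterministically: larger extent first, then concept id.
#' Scores are computed exactly and reported rounded half-up to `digits`
#' decimals (column `score`), with the unrounded value in `score_exact`.
#'
#' @param lattice a `concept_lattice`, or a list of [formal_concept()]s
#'   forming the knowledge base.
#' @param query a [formal_concept()] (see [query_from_attributes()]) or a
#'   character vector of attribute names.
#' @param alpha,beta similarity weights; defaults `alpha = 0`, `beta = 1`.
#' @param top_k number of results to return (>= 1).
#' @param include_empty_extent include concepts with empty extents.
#' @param digits decimal places for the displayed score (default 3).
#' @return data.frame of class `fcakb_retrieval` with columns `rank`,
#'   `concept_id`, `n_objects`, `objects`, `score`, `score_exact`,
#'   `shared_attributes`, `distinguishing_attributes`.
#' @examples
#' kb <- crc_demo_kb()
#' res <- retrieve_similar(kb, crc_demo_query(), top_k = 10)
#' res$score   # 1.000 0.818 0.818 0.727 ...
#' @export
retrieve_similar <- function(lattice, query, alpha = 0, beta = 1, top_k = 10,
                             include_empty_extent = FALSE, digits = 3) {
  check_params(alpha, beta)
  if (!is.numeric(top_k) || length(top_k) != 1 || is.na(top_k) || top_k < 1) {
    stop_validation("top_k must be a positive integer")
  }
  concepts <- if (inherits(lattice, "concept_lattice")) lattice$concepts else lattice
  if (is.character(query)) {
    universe <- if (inherits(lattice, "concept_lattice")) {
      lattice$context$attributes
    } else {
      sort(unique(unlist(lapply(concepts, `[[`, "intent"))))
    }
    query <- formal_concept(character(0),
                            normalize_attributes(query, universe), id = "query")
  }
  if (!include_empty_extent) {
    concepts <- Filter(function(co) length(co$extent) > 0, concepts)
  }
  if (!length(concepts)) stop_validation("no concepts to score")
  score <- vapply(concepts, concept_similarity, numeric(1),
                  c2 = query, alpha = alpha, beta = beta)
  esize <- vapply(concepts, function(co) length(co$extent), 0L)
  ids <- vapply(seq_along(concepts), function(i) {
    concepts[[i]]$id %||% sprintf("C%d", i)
  }, "")
  idr <- integer(length(ids)); idr[order_ids_natural(ids)] <- seq_along(ids)
  ord <- order(-score, -esize, idr)
  keep <- utils::head(ord, top_k)
  res <- data.frame(
    rank = seq_along(keep),
    concept_id = ids[keep],
    n_objects = esize[keep],
    objects = vapply(concepts[keep], function(co) set_label(co$extent), ""),
    score = round_half_up(score[keep], digits),
    score_exact = score[keep],
    shared_attributes = vapply(concepts[keep], function(co) {
      set_label(intersect(co$intent, query$intent))
    }, ""),
    distinguishing_attributes = vapply(concepts[keep], function(co) {
      set_label(setdiff(co$intent, query$intent))
    }, ""),
    stringsAsFactors = FALSE
  )
  class(res) <- c("fcakb_retrieval", "data.frame")
  res
}

#' @export
print.fcakb_retrieval <- function(x, ...) {
  cat(sprintf("Top %d similar concepts:\n", nrow(x)))
  out <- data.frame(rank = x$rank, concept = x$concept_id,
                    objects = ifelse(nchar(x$objects) > 0 & x$n_objects <= 8,
                                     x$objects, as.character(x$n_objects)),
                    score = format(x$score, nsmall = 3),
                    stringsAsFactors = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Ranked retrieval as prediction on a fitted lattice
#'
#' `predict()` on a `concept_lattice` performs case retrieval for new
#' patients: `newdata` may be a character vector of binary attribute names, a
#' [formal_concept()] query, or a data.frame of raw patient records (which is
#' binarized with `scheme` first). Returns one retrieval table per query
#' (a single table if there is one query).
#'
#' @param object a `concept_lattice`.
#' @param newdata attributes, query concept, or raw patient records.
#' @param scheme coding scheme used when `newdata` is a raw record table.
#' @param ... passed to [retrieve_similar()] (`alpha`, `beta`, `top_k`, ...).
#' @return an `fcakb_retrieval` data.frame, or a named list of them for
#'   multi-row `newdata`.
#' @export
predict.concept_lattice <- function(object, newdata,
                                    scheme = crc_coding_scheme(), ...) {
  if (is.data.frame(newdata)) {
    validate_patient_records(newdata)
    out <- lapply(seq_len(nrow(newdata)), function(i) {
      v <- binarize_record(as.list(newdata[i, ]), scheme)
      retrieve_similar(object, names(v)[v == 1], ...)
    })
    names(out) <- newdata$patient_id
    if (length(out) == 1) out[[1]] else out
  } else {
    retrieve_similar(object, newdata, ...)
  }
}
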