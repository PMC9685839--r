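#' Formal contexts
#'
#' A formal context is a triple (G, M, I): a set of objects G, a set of
#' attributes M, and a binary incidence relation I stating which object has
#' which attribute. It is the tabular input from which all formal concepts are
#' derived.
#'
#' @param incidence a logical or 0/1 numeric matrix (objects in rows,
#'   attributes in columns), or a data.frame of 0/1 columns.
#' @param objects character vector of unique object identifiers; defaults to
#'   the row names of `incidence`.
#' @param attributes character vector of unique attribute names; defaults to
#'   the column names of `incidence`.
#' @return an object of class `formal_context` with fields `objects`,
#'   `attributes` and `incidence` (a named logical matrix).
#' @examples
#' ctx <- formal_context(rbind(P1 = c(1, 0, 1), P2 = c(0, 1, 1)),
#'                       attributes = c("a", "b", "c"))
#' intent_of(ctx, c("P1", "P2"))
#' @seealso [intent_of()], [extent_of()], [concept_lattice()]
#' @export
formal_context <- function(incidence, objects = NULL, attributes = NULL) {
  if (is.data.frame(incidence)) incidence <- as.matrix(incidence)
  if (!is.matrix(incidence)) stop_validation("incidence must be a matrix")
  objects <- as.character(objects %||% rownames(incidence) %||%
                            paste0("g", seq_len(nrow(incidence))))
  attributes <- as.character(attributes %||% colnames(incidence) %||%
                               paste0("m", seq_len(ncol(incidence))))
  if (length(objects) != nrow(incidence) || length(attributes) != ncol(incidence)) {
    stop_validation("incidence dimensions do not match object/attribute names")
  }
  if (anyDuplicated(objects)) {
    stop_validation(sprintf("duplicate object ids: %s",
                            set_label(unique(objects[duplicated(objects)]))))
  }
  if (anyDuplicated(attributes)) {
    stop_validation(sprintf("duplicate attribute names: %s",
                            set_label(unique(attributes[duplicated(attributes)]))))
  }
  storage.mode(incidence) <- "double"
  if (anyNA(incidence) || !all(incidence %in% c(0, 1))) {
    stop_validation("incidence cells must all be 0 or 1")
  }
  I <- incidence == 1
  dimnames(I) <- list(objects, attributes)
  structure(list(objects = objects, attributes = attributes, incidence = I),
            class = "formal_context")
}

#' @export
print.formal_context <- function(x, ...) {
  cat(sprintf("Formal context: %d objects x %d attributes, density %.3f\n",
              length(x$objects), length(x$attributes), mean(x$incidence)))
  n <- min(6L, length(x$objects))
  m <- min(10L, length(x$attributes))
  if (n > 0 && m > 0) {
    shown <- ifelse(x$incidence[seq_len(n), seq_len(m), drop = FALSE], "X", ".")
    print(shown, quote = FALSE)
    if (n < length(x$objects) || m < length(x$attributes)) cat("...\n")
  }
  invisible(x)
}

#' @export
dim.formal_context <- function(x) dim(x$incidence)

## Resolve user-supplied object ids to row indices.
resolve_objects <- function(context, objects) {
  if (is.null(objects) || length(objects) == 0) return(integer(0))
  idx <- match(as.character(objects), context$objects)
  if (anyNA(idx)) {
    stop_lookup(sprintf("unknown object id(s): %s",
                        set_label(unique(objects[is.na(idx)]))))
  }
  idx
}

## Attribute spelling aliases seen in the source tables; resolution is
## case-insensitive against the context's canonical names on top of these.
.attribute_aliases <- c(
  Ly_N = "Lv_N", Ly_Y = "Lv_Y", LymH = "Lym_H", LymL = "Lym_L",
  age_L = "Age_L", age_M = "Age_M", age_H = "Age_H", Mad = "MAd"
)

#' Normalize attribute names against a canonical universe
#'
#' Attribute tokens from external files and queries are matched
#' case-insensitively and through a small table of spelling variants
#' (`Ly_N`/`Lv_N`, `LymH`/`Lym_H`, ...) so the same clinical attribute always
#' maps to one canonical name.
#'
#' @param x character vector of attribute tokens.
#' @param universe canonical attribute names to resolve against.
#' @return `x` with every token replaced by its canonical spelling.
#' @export
normalize_attributes <- function(x, universe) {
  x <- as.character(x)
  ali <- match(x, names(.attribute_aliases))
  x[!is.na(ali)] <- .attribute_aliases[ali[!is.na(ali)]]
  idx <- match(x, universe)
  ci <- match(tolower(x), tolower(universe))
  idx[is.na(idx)] <- ci[is.na(idx)]
  if (anyNA(idx)) {
    stop_lookup(sprintf("unknown attribute name(s): %s",
                        set_label(unique(x[is.na(idx)]))))
  }
  universe[idx]
}

resolve_attributes <- function(context, attributes) {
  if (is.null(attributes) || length(attributes) == 0) return(integer(0))
  match(normalize_attributes(attributes, context$attributes), context$attributes)
}

#' Derivation operators and closure
#'
#' The two derivation operators of a formal context form a Galois connection:
#' `intent_of(ctx, A)` returns all attributes shared by every object in `A`
#' (A'), and `extent_of(ctx, B)` returns all objects possessing every
#' attribute in `B` (B'). Their composition `closure(ctx, B)` = B'' is a
#' closure operator on attribute sets; its fixed points are exactly the
#' concept intents. By the usual universal-quantifier convention,
#' `intent_of(ctx, character(0))` is all of M and `extent_of(ctx,
#' character(0))` is all of G.
#'
#' @param context a [formal_context()].
#' @param objects character vector of object ids (a subset A of G).
#' @param attributes character vector of attribute names (a subset B of M).
#' @return `intent_of` and `closure` return a character vector of attributes
#'   in the context's canonical order; `extent_of` returns a character vector
#'   of object ids in canonical order.
#' @examples
#' ctx <- crc_demo_context()
#' intent_of(ctx, c("P2", "P3"))   # {Age_M, Lym_H}
#' extent_of(ctx, "CEA_H")         # {P1, P3}
#' closure(ctx, "Age_M")           # {Age_M, Lym_H}
#' @export
intent_of <- function(context, objects) {
  idx <- resolve_objects(context, objects)
  if (length(idx) == 0) return(context$attributes)
  sub <- context$incidence[idx, , drop = FALSE]
  context$attributes[colSums(sub) == length(idx)]
}

#' @rdname intent_of
#' @export
extent_of <- function(context, attributes) {
  idx <- resolve_attributes(context, attributes)
  if (length(idx) == 0) return(context$objects)
  sub <- context$incidence[, idx, drop = FALSE]
  context$objects[rowSums(sub) == length(idx)]
}

#' @rdname intent_of
#' @export
closure <- function(context, attributes) {
  intent_of(context, extent_of(context, attributes))
}

#' Test whether an (extent, intent) pair is a formal concept
#'
#' `(A, B)` is a formal concept iff A' = B and B' = A, i.e. the pair is a
#' fixed point of the Galois connection.
#'
#' @inheritParams intent_of
#' @param extent candidate extent (character vector of object ids).
#' @param intent candidate intent (character vector of attribute names).
#' @return `TRUE` or `FALSE`.
#' @examples
#' ctx <- crc_demo_context()
#' is_concept(ctx, c("P1", "P3"), "CEA_H")           # TRUE
#' is_concept(ctx, c("P2", "P3"), "Age_M")           # FALSE: intent not closed
#' @export
is_concept <- function(context, extent, intent) {
  A <- sort(unique(context$objects[resolve_objects(context, extent)]))
  B <- sort(unique(context$attributes[resolve_attributes(context, intent)]))
  identical(sort(intent_of(context, A)), B) &&
    identical(sort(extent_of(context, B)), A)
}
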