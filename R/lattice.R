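## Concept enumeration (NextClosure) and Hasse structure.
##
## Intents are handled as logical masks over the context's canonical
## attribute order; extents as integer row-index sets. The closure B -> B''
## is evaluated with two BLAS products against the dense incidence matrix,
## which keeps the full 2442-patient lattice (tens of thousands of concepts)
## tractable in plain R.

## closure of an attribute mask; returns the closed mask and its extent.
close_mask <- function(Id, b) {
  k <- sum(b)
  ext <- if (k == 0) rep(1, nrow(Id)) else as.numeric((Id %*% b) == k)
  ne <- sum(ext)
  b2 <- if (ne == 0) rep(TRUE, ncol(Id)) else as.vector(crossprod(Id, ext)) == ne
  list(intent = b2, extent = which(ext == 1))
}

## All closed intents in lectic order (Ganter's NextClosure), with extents.
## Attribute 1 is the most significant in the lectic order.
next_closure_intents <- function(context) {
  Id <- context$incidence
  storage.mode(Id) <- "double"
  M <- ncol(Id)
  intents <- list(); extents <- list()
  cur <- close_mask(Id, rep(0, M))
  intents[[1]] <- cur$intent; extents[[1]] <- cur$extent
  A <- cur$intent
  n <- 1L
  while (!all(A)) {
    for (i in M:1) {
      if (A[i]) next
      b <- A
      if (i < M) b[(i + 1L):M] <- FALSE
      b[i] <- TRUE
      cand <- close_mask(Id, as.numeric(b))
      Cm <- cand$intent
      # accept the closure only if it adds no attribute before position i
      if (i == 1L || !any(Cm[seq_len(i - 1L)] & !A[seq_len(i - 1L)])) {
        A <- Cm
        n <- n + 1L
        intents[[n]] <- Cm
        extents[[n]] <- cand$extent
        break
      }
    }
  }
  list(intents = intents, extents = extents)
}

## Pack logical intent masks (rows of `mat`) into 16-bit integer words so
## subset tests between intents are a handful of bitwAnd ops regardless of M.
pack_masks <- function(mat) {
  M <- ncol(mat)
  nw <- max(1L, as.integer(ceiling(M / 16)))
  W <- matrix(0L, nrow(mat), nw)
  for (w in seq_len(nw)) {
    cols <- ((w - 1L) * 16L + 1L):min(w * 16L, M)
    pow <- 2L^(seq_along(cols) - 1L)
    W[, w] <- as.integer(mat[, cols, drop = FALSE] %*% pow)
  }
  W
}

## Covering edges of a complete concept set given its intent masks.
## (u covers v) iff intent(u) is a maximal strict subset of intent(v).
covers_from_masks <- function(mat, ids) {
  n <- nrow(mat)
  if (n <= 1) return(data.frame(upper = character(0), lower = character(0)))
  W <- pack_masks(mat)
  nw <- ncol(W)
  sizes <- rowSums(mat)
  upper <- integer(0); lower <- integer(0)
  for (v in seq_len(n)) {
    sub <- rep(TRUE, n)
    for (w in seq_len(nw)) sub <- sub & bitwAnd(W[, w], W[v, w]) == W[, w]
    sub[v] <- FALSE
    cand <- which(sub)
    if (!length(cand)) next
    cand <- cand[order(-sizes[cand])]
    acc <- integer(0)
    for (u in cand) {
      dominated <- FALSE
      for (a in acc) {
        ok <- TRUE
        for (w in seq_len(nw)) {
          if (bitwAnd(W[u, w], W[a, w]) != W[u, w]) { ok <- FALSE; break }
        }
        if (ok) { dominated <- TRUE; break }
      }
      if (!dominated) acc <- c(acc, u)
    }
    upper <- c(upper, acc)
    lower <- c(lower, rep.int(v, length(acc)))
  }
  data.frame(upper = ids[upper], lower = ids[lower], stringsAsFactors = FALSE)
}

#' A single formal concept
#'
#' Lightweight container pairing an extent (object ids) with an intent
#' (attribute names). Used for externally supplied concept lists (e.g. a
#' published knowledge-base excerpt) and for retrieval queries.
#'
#' @param extent character vector of object ids (may be empty for queries).
#' @param intent character vector of attribute names.
#' @param id optional stable identifier.
#' @return an object of class `formal_concept`.
#' @export
formal_concept <- function(extent, intent, id = NULL) {
  structure(list(id = id %||% NA_character_,
                 extent = as.character(extent),
                 intent = as.character(intent)),
            class = "formal_concept")
}

#' @export
print.formal_concept <- function(x, ...) {
  cat(sprintf("<%s> ({%s}, {%s})\n", x$id, set_label(x$extent), set_label(x$intent)))
  invisible(x)
}

#' Enumerate the concept lattice of a formal context
#'
#' Enumerates every formal concept (A, B) with A' = B and B' = A using the
#' NextClosure algorithm over attribute sets in the context's canonical
#' order, then computes the Hasse diagram (the covering relation, i.e. the
#' transitive reduction of the subconcept order). The result always contains
#' the top concept (all objects, `closure(ctx, character(0))`) and the bottom
#' concept (`extent_of(ctx, M)`, all attributes shared by it).
#'
#' Concepts are sorted by extent size (descending) then intent
#' (lexicographically on the attribute bit pattern), and ids `C1`, `C2`, ...
#' are assigned after sorting, so ids are reproducible across runs.
#'
#' @param context a [formal_context()].
#' @param covers compute the covering edges (default `TRUE`); skip for very
#'   large lattices where only the concept set is needed.
#' @return an object of class `concept_lattice`: a list with the `context`,
#'   `concepts` (list of [formal_concept()]s), `cover_edges` (data.frame with
#'   columns `upper`, `lower`), and internal index structures.
#' @examples
#' lat <- concept_lattice(crc_demo_context())
#' lat                      # 7 concepts, 5 with nonempty extent and intent
#' summary(lat)
#' @seealso [proper_concept_count()], [retrieve_similar()],
#'   [brute_force_concepts()]
#' @export
concept_lattice <- function(context, covers = TRUE) {
  if (!inherits(context, "formal_context")) {
    stop_validation("context must be a formal_context")
  }
  enum <- next_closure_intents(context)
  n <- length(enum$intents)
  imat <- do.call(rbind, enum$intents)
  esize <- lengths(enum$extents)
  # canonical order: extent size desc, then intent bit pattern
  key <- apply(imat, 1, function(b) rawToChar(as.raw(48L + b)))
  ord <- order(-esize, key)
  imat <- imat[ord, , drop = FALSE]
  extents <- enum$extents[ord]
  ids <- sprintf("C%d", seq_len(n))
  concepts <- lapply(seq_len(n), function(i) {
    formal_concept(context$objects[extents[[i]]],
                   context$attributes[imat[i, ]], id = ids[i])
  })
  edges <- if (covers) covers_from_masks(imat, ids) else NULL
  structure(list(context = context, concepts = concepts, cover_edges = edges,
                 intent_matrix = imat, extent_index = extents,
                 extent_sizes = lengths(extents)),
            class = "concept_lattice")
}

#' @export
print.concept_lattice <- function(x, ...) {
  cat(sprintf("Concept lattice: %d concepts (%d with nonempty extent and intent)\n",
              length(x$concepts), proper_concept_count(x)))
  cat(sprintf("  context: %d objects x %d attributes\n",
              length(x$context$objects), length(x$context$attributes)))
  if (!is.null(x$cover_edges)) {
    cat(sprintf("  Hasse diagram: %d covering edges\n", nrow(x$cover_edges)))
  }
  invisible(x)
}

#' @export
summary.concept_lattice <- function(object, n = 10, ...) {
  print(object)
  k <- min(n, length(object$concepts))
  cat(sprintf("First %d concepts:\n", k))
  for (i in seq_len(k)) {
    co <- object$concepts[[i]]
    cat(sprintf("  %-5s |A|=%-4d {%s}\n", co$id, length(co$extent),
                set_label(co$intent)))
  }
  invisible(object)
}

#' Brute-force concept enumeration (testing oracle)
#'
#' Closes every subset of the attribute powerset and deduplicates — an
#' independent, exhaustive route to the same concept set, used to verify the
#' NextClosure enumeration on small contexts. Guarded at 20 attributes.
#'
#' @inheritParams concept_lattice
#' @return list of [formal_concept()]s sorted by (extent size descending,
#'   intent bit pattern), ids assigned after sorting.
#' @export
brute_force_concepts <- function(context) {
  M <- length(context$attributes)
  if (M > 20) stop_size("brute force is guarded at 20 attributes")
  Id <- context$incidence
  storage.mode(Id) <- "double"
  seen <- new.env(parent = emptyenv())
  intents <- list(); extents <- list()
  for (code in 0:(2^M - 1)) {
    b <- as.numeric(bitwAnd(bitwShiftR(code, 0:(M - 1)), 1L))
    cl <- close_mask(Id, b)
    keyc <- rawToChar(as.raw(48L + cl$intent))
    if (is.null(seen[[keyc]])) {
      seen[[keyc]] <- TRUE
      intents[[length(intents) + 1L]] <- cl$intent
      extents[[length(extents) + 1L]] <- cl$extent
    }
  }
  key <- vapply(intents, function(b) rawToChar(as.raw(48L + b)), "")
  ord <- order(-lengths(extents), key)
  lapply(seq_along(ord), function(i) {
    j <- ord[i]
    formal_concept(context$objects[extents[[j]]],
                   context$attributes[intents[[j]]], id = sprintf("C%d", i))
  })
}

#' Covering (Hasse) edges of a concept set
#'
#' Computes the transitive reduction of the subconcept order: edge
#' (upper, lower) iff extent(lower) is strictly contained in extent(upper)
#' with no concept strictly in between.
#'
#' @param concepts a `concept_lattice` or a complete list of
#'   [formal_concept()]s of one context.
#' @return data.frame with columns `upper` and `lower` (concept ids).
#' @export
covering_edges <- function(concepts) {
  if (inherits(concepts, "concept_lattice")) {
    if (!is.null(concepts$cover_edges)) return(concepts$cover_edges)
    return(covers_from_masks(concepts$intent_matrix,
                             vapply(concepts$concepts, `[[`, "", "id")))
  }
  universe <- sort(unique(unlist(lapply(concepts, `[[`, "intent"))))
  exts <- lapply(concepts, function(co) sort(co$extent))
  if (anyDuplicated(vapply(exts, paste, "", collapse = "\r"))) {
    stop_validation("duplicate extents: not a valid concept set")
  }
  mat <- do.call(rbind, lapply(concepts, function(co) universe %in% co$intent))
  ids <- vapply(seq_along(concepts), function(i) {
    concepts[[i]]$id %||% sprintf("C%d", i)
  }, "")
  covers_from_masks(mat, ids)
}

#' Subconcept test
#'
#' `c1` is a subconcept of `c2` iff extent(c1) is a subset of extent(c2)
#' (equivalently, intent(c2) is a subset of intent(c1)).
#'
#' @param c1,c2 [formal_concept()]s over the same context.
#' @return `TRUE` or `FALSE`.
#' @export
subconcept_of <- function(c1, c2) {
  all(c1$extent %in% c2$extent)
}

#' Count concepts with nonempty extent and nonempty intent
#'
#' The full lattice always carries a top concept (often with empty intent)
#' and a bottom concept (often with empty extent); this "proper" count
#' excludes any concept with an empty side, which is the count quoted for
#' small worked examples.
#'
#' @param lattice a `concept_lattice`.
#' @return integer count.
#' @export
proper_concept_count <- function(lattice) {
  sum(vapply(lattice$concepts,
             function(co) length(co$extent) > 0 && length(co$intent) > 0,
             logical(1)))
}

#' Extract concepts as a data.frame
#'
#' @param x a `concept_lattice`.
#' @param row.names,optional unused, for generic consistency.
#' @param max_listed_objects list object ids only for concepts with at most
#'   this many objects (larger extents are summarized by their count).
#' @param ... unused.
#' @return data.frame with columns `concept_id`, `attributes`, `n_objects`,
#'   `objects`.
#' @export
as.data.frame.concept_lattice <- function(x, row.names = NULL, optional = FALSE,
                                          max_listed_objects = 2, ...) {
  data.frame(
    concept_id = vapply(x$concepts, `[[`, "", "id"),
    attributes = vapply(x$concepts, function(co) set_label(co$intent), ""),
    n_objects = vapply(x$concepts, function(co) length(co$extent), 0L),
    objects = vapply(x$concepts, function(co) {
      if (length(co$extent) <= max_listed_objects) set_label(co$extent) else ""
    }, ""),
    stringsAsFactors = FALSE
  )
}

#' Plot a concept lattice as a layered Hasse diagram
#'
#' Concepts are laid out in layers by intent size (the top concept at the
#' top) with covering edges drawn between layers. Intended for small
#' lattices; use [export_lattice()]'s DOT output for large ones.
#'
#' @param x a `concept_lattice` (with covering edges).
#' @param labels label nodes with concept ids (default) and intent size.
#' @param ... passed to [graphics::plot()].
#' @export
plot.concept_lattice <- function(x, labels = TRUE, ...) {
  if (is.null(x$cover_edges)) stop_validation("lattice was built without covers")
  sizes <- rowSums(x$intent_matrix)
  layer <- match(sizes, sort(unique(sizes)))
  xs <- numeric(length(layer))
  for (l in unique(layer)) {
    k <- which(layer == l)
    xs[k] <- seq_along(k) / (length(k) + 1)
  }
  ys <- 1 - (layer - 1) / max(1, max(layer) - 1)
  graphics::plot(xs, ys, xlim = c(0, 1), ylim = c(-0.05, 1.05), axes = FALSE,
                 xlab = "", ylab = "", pch = 21, bg = "grey85", cex = 2.2, ...)
  ids <- vapply(x$concepts, `[[`, "", "id")
  e <- x$cover_edges
  if (nrow(e)) {
    iu <- match(e$upper, ids); il <- match(e$lower, ids)
    graphics::segments(xs[iu], ys[iu], xs[il], ys[il], col = "grey55")
    graphics::points(xs, ys, pch = 21, bg = "grey85", cex = 2.2)
  }
  if (labels) graphics::text(xs, ys, ids, cex = 0.65)
  invisible(x)
}
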