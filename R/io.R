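## Context and lattice file I/O.
##
## csv01: header row of attribute names (first column = object id column),
## one row per object, cells 0/1. cxt: the Burmeister interchange dialect
## ("B" magic line, object/attribute counts, names, rows of '.'/'X').
## write -> read is bit-exact on (G, M, I), including ordering.

guess_context_format <- function(path) {
  if (grepl("\\.cxt$", path, ignore.case = TRUE)) "cxt" else "csv01"
}

#' Read and write formal contexts
#'
#' Supports two plain-text formats: `csv01` (CSV with a header of attribute
#' names, first column object ids, cells 0/1) and `cxt` (the Burmeister
#' format used by FCA tools: a `B` magic line, object and attribute counts,
#' the names, then one `.`/`X` row per object). `format = "auto"` picks by
#' file extension (`.cxt` vs anything else). A write followed by a read
#' reproduces the context exactly, including object/attribute order.
#'
#' @param path file path.
#' @param format `"auto"`, `"csv01"` or `"cxt"`.
#' @return `read_context` returns a [formal_context()]; `write_context`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".cxt")
#' write_context(crc_demo_context(), f)
#' read_context(f)
#' @export
read_context <- function(path, format = c("auto", "csv01", "cxt")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_context_format(path)
  if (!file.exists(path)) stop_format(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "csv01") read_context_csv01(lines) else read_context_cxt(lines)
}

read_context_csv01 <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format("csv01: empty file")
  cells <- strsplit(lines, ",", fixed = TRUE)
  cells <- lapply(cells, trimws)
  header <- cells[[1]]
  if (length(header) < 2) stop_format("csv01 line 1: header needs an id column and at least one attribute")
  attributes <- header[-1]
  n <- length(cells) - 1L
  I <- matrix(0, n, length(attributes))
  objects <- character(n)
  for (i in seq_len(n)) {
    row <- cells[[i + 1L]]
    if (length(row) != length(header)) {
      stop_format(sprintf("csv01 line %d: expected %d cells, found %d",
                          i + 1L, length(header), length(row)))
    }
    objects[i] <- row[1]
    v <- row[-1]
    if (!all(v %in% c("0", "1"))) {
      stop_format(sprintf("csv01 line %d: non-binary cell %s", i + 1L,
                          dQuote(v[!v %in% c("0", "1")][1], q = FALSE)))
    }
    I[i, ] <- as.numeric(v)
  }
  formal_context(I, objects, attributes)
}

read_context_cxt <- function(lines) {
  if (!length(lines) || trimws(lines[1]) != "B") {
    stop_format("cxt line 1: expected Burmeister magic line 'B'")
  }
  body <- lines[-1]
  lineno <- which(nzchar(trimws(body))) + 1L  # original line numbers
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop_format("cxt: missing object/attribute counts")
  counts <- suppressWarnings(as.integer(trimws(body[1:2])))
  if (anyNA(counts) || any(counts < 0)) {
    stop_format(sprintf("cxt line %d: invalid count", lineno[which(is.na(counts))[1]]))
  }
  nG <- counts[1]; nM <- counts[2]
  need <- 2L + nG + nM + nG
  if (length(body) < need) {
    stop_format(sprintf("cxt: declares %d objects and %d attributes but has %d content lines (%d required)",
                        nG, nM, length(body), need))
  }
  objects <- trimws(body[2L + seq_len(nG)])
  attributes <- trimws(body[2L + nG + seq_len(nM)])
  I <- matrix(0, nG, nM)
  for (i in seq_len(nG)) {
    row <- body[2L + nG + nM + i]
    ch <- strsplit(row, "")[[1]]
    if (length(ch) != nM || !all(ch %in% c(".", "X", "x"))) {
      stop_format(sprintf("cxt line %d: incidence row must be %d characters of '.' or 'X'",
                          lineno[2L + nG + nM + i], nM))
    }
    I[i, ] <- as.numeric(ch %in% c("X", "x"))
  }
  formal_context(I, objects, attributes)
}

#' @rdname read_context
#' @param context a [formal_context()] to write.
#' @export
write_context <- function(context, path, format = c("auto", "csv01", "cxt")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_context_format(path)
  I <- context$incidence
  if (format == "csv01") {
    lines <- c(paste(c("object", context$attributes), collapse = ","),
               vapply(seq_len(nrow(I)), function(i) {
                 paste(c(context$objects[i], as.integer(I[i, ])), collapse = ",")
               }, ""))
  } else {
    lines <- c("B", "", nrow(I), ncol(I), "", context$objects,
               context$attributes,
               vapply(seq_len(nrow(I)), function(i) {
                 paste(ifelse(I[i, ], "X", "."), collapse = "")
               }, ""))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a concept lattice to CSV or DOT
#'
#' `concepts_csv` writes one row per concept (`concept_id`, the comma-joined
#' attribute set, the object count, and the object ids when the count is at
#' most `max_listed_objects`). `dot` writes a Graphviz digraph with one node
#' per concept (labeled with extent/intent sizes) and one edge per covering
#' pair, for rendering the Hasse diagram.
#'
#' @param lattice a `concept_lattice`.
#' @param path output file path.
#' @param format `"concepts_csv"` or `"dot"`.
#' @param max_listed_objects object-id listing threshold for `concepts_csv`
#'   (default 2).
#' @return `path`, invisibly.
#' @export
export_lattice <- function(lattice, path, format = c("concepts_csv", "dot"),
                           max_listed_objects = 2) {
  format <- match.arg(format)
  if (format == "concepts_csv") {
    df <- as.data.frame(lattice, max_listed_objects = max_listed_objects)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    edges <- lattice$cover_edges %||% covering_edges(lattice)
    lines <- c("digraph concept_lattice {", "  rankdir=TB;",
               "  node [shape=ellipse, fontsize=10];")
    for (co in lattice$concepts) {
      lines <- c(lines, sprintf("  %s [label=\"%s\\n|A|=%d |B|=%d\"];",
                                co$id, co$id, length(co$extent), length(co$intent)))
    }
    if (nrow(edges)) {
      lines <- c(lines, sprintf("  %s -> %s;", edges$upper, edges$lower))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read and write lattices as JSON
#'
#' The JSON document stores the context (objects, attributes, incidence rows
#' as 0/1 strings), the concept list, and the covering edges; it is the
#' machine boundary between the lattice-building and retrieval stages of the
#' command-line workflow.
#'
#' @param lattice a `concept_lattice`.
#' @param path file path.
#' @return `read_lattice_json` returns a `concept_lattice`;
#'   `write_lattice_json` returns `path` invisibly.
#' @export
write_lattice_json <- function(lattice, path) {
  inc <- lattice$context$incidence
  doc <- list(
    context = list(
      objects = lattice$context$objects,
      attributes = lattice$context$attributes,
      rows = vapply(seq_len(nrow(inc)), function(i) {
        paste(as.integer(inc[i, ]), collapse = "")
      }, "")
    ),
    concepts = lapply(lattice$concepts, function(co) {
      list(id = co$id, extent = I(co$extent), intent = I(co$intent))
    }),
    cover_edges = lattice$cover_edges %||% data.frame(upper = character(0),
                                                      lower = character(0))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lattice_json
#' @export
read_lattice_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  att <- as.character(doc$context$attributes)
  obj <- as.character(doc$context$objects)
  I <- do.call(rbind, lapply(doc$context$rows, function(r) {
    as.numeric(strsplit(r, "")[[1]])
  }))
  context <- formal_context(I, obj, att)
  conc <- doc$concepts
  concepts <- lapply(seq_len(nrow(conc)), function(i) {
    formal_concept(unlist(conc$extent[[i]]) %||% character(0),
                   unlist(conc$intent[[i]]) %||% character(0),
                   id = conc$id[i])
  })
  imat <- do.call(rbind, lapply(concepts, function(co) att %in% co$intent))
  eidx <- lapply(concepts, function(co) match(co$extent, obj))
  edges <- as.data.frame(doc$cover_edges)
  if (!nrow(edges)) edges <- data.frame(upper = character(0), lower = character(0))
  structure(list(context = context, concepts = concepts, cover_edges = edges,
                 intent_matrix = imat, extent_index = eidx,
                 extent_sizes = lengths(eidx)),
            class = "concept_lattice")
}
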