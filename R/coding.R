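## One-hot coding of raw colorectal-cancer records into the 32-attribute
## binary space: 11 mutually exclusive, exhaustive attribute groups.

.patient_fields <- c("patient_id", "age", "differentiation", "histology",
                     "lymph_node_count", "cea", "ca199", "lvi", "lnr",
                     "t_stage", "n_stage", "stage_group")

.differentiation_levels <- c("poor", "moderate", "well")
.histology_levels <- c("mucinous_adenocarcinoma", "adenocarcinoma")
.t_levels <- c("T1", "T2", "T3", "T4")
.n_levels <- c("N0", "N1", "N2")
.stage_levels <- c("I", "IIA", "IIB", "IIC", "IIIA", "IIIB", "IIIC")

#' The colorectal-cancer one-hot coding scheme
#'
#' Defines the 32 binary attributes (11 groups) used to binarize a raw
#' patient record. Within each group exactly one attribute fires, so every
#' coded row sums to 11. Cutoffs follow standard clinical practice: low bins
#' are half-open below the cutoff and the cutoff itself falls in the upper
#' bin (age 60 -> `Age_M`, CEA 5 -> `CEA_H`, LNR 0.13 -> `LNR_H`, 10 nodes
#' -> `Lym_H`, CA19-9 37 -> `Ca199_H`; `Age_H` is age >= 70).
#'
#' Groups, in canonical column order:
#' age (`Age_L`/`Age_M`/`Age_H`), differentiation (`Degre_L` = poor,
#' `Degre_M` = moderate, `Degre_H` = well), histology (`MAd`/`Ad`), T stage
#' (`T1`-`T4`), N stage (`N0`-`N2`), examined lymph nodes (`Lym_L`/`Lym_H`),
#' CEA (`CEA_L`/`CEA_H`), CA19-9 (`Ca199_L`/`Ca199_H`), lymphovascular
#' invasion (`Lv_N`/`Lv_Y`), lymph-node ratio (`LNR_L`/`LNR_H`), and stage
#' group (`I`, `IIA`, `IIB`, `IIC`, `IIIA`, `IIIB`, `IIIC`).
#'
#' @return an object of class `coding_scheme`: a list of attribute groups,
#'   each with a name, its attribute names, and the predicate assigning a
#'   record to one attribute.
#' @seealso [binarize_record()], [build_context()]
#' @export
crc_coding_scheme <- function() {
  cut2 <- function(field, cutoff) {
    force(field); force(cutoff)
    function(r) if (r[[field]] < cutoff) 1L else 2L
  }
  level_code <- function(field, levels) {
    force(field); force(levels)
    function(r) match(r[[field]], levels)
  }
  groups <- list(
    list(name = "age", attributes = c("Age_L", "Age_M", "Age_H"),
         code = function(r) if (r$age < 60) 1L else if (r$age < 70) 2L else 3L),
    list(name = "differentiation", attributes = c("Degre_L", "Degre_M", "Degre_H"),
         code = level_code("differentiation", .differentiation_levels)),
    list(name = "histology", attributes = c("MAd", "Ad"),
         code = level_code("histology", .histology_levels)),
    list(name = "t_stage", attributes = .t_levels,
         code = level_code("t_stage", .t_levels)),
    list(name = "n_stage", attributes = .n_levels,
         code = level_code("n_stage", .n_levels)),
    list(name = "lymph_nodes", attributes = c("Lym_L", "Lym_H"),
         code = cut2("lymph_node_count", 10)),
    list(name = "cea", attributes = c("CEA_L", "CEA_H"), code = cut2("cea", 5)),
    list(name = "ca199", attributes = c("Ca199_L", "Ca199_H"),
         code = cut2("ca199", 37)),
    list(name = "lvi", attributes = c("Lv_N", "Lv_Y"),
         code = function(r) if (isTRUE(r$lvi)) 2L else 1L),
    list(name = "lnr", attributes = c("LNR_L", "LNR_H"), code = cut2("lnr", 0.13)),
    list(name = "stage_group", attributes = .stage_levels,
         code = level_code("stage_group", .stage_levels))
  )
  structure(list(groups = groups), class = "coding_scheme")
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat(sprintf("Coding scheme: %d groups, %d binary attributes\n",
              length(x$groups), length(scheme_attributes(x))))
  for (g in x$groups) cat(sprintf("  %-16s %s\n", g$name, set_label(g$attributes)))
  invisible(x)
}

#' Attribute names of a coding scheme, in canonical order
#' @param scheme a [crc_coding_scheme()].
#' @return character vector of attribute names.
#' @export
scheme_attributes <- function(scheme) {
  unlist(lapply(scheme$groups, `[[`, "attributes"), use.names = FALSE)
}

## Field-level checks shared by the parser and the binarizer. Returns NULL or
## a message naming the offending field.
check_record_fields <- function(r) {
  miss <- setdiff(.patient_fields, names(r))
  if (length(miss)) return(sprintf("missing field(s): %s", set_label(miss)))
  num <- c(age = r$age, lymph_node_count = r$lymph_node_count,
           cea = r$cea, ca199 = r$ca199, lnr = r$lnr)
  if (anyNA(num) || !is.numeric(num)) {
    bad <- names(num)[!is.finite(num)]
    return(sprintf("non-numeric or missing value in: %s", set_label(bad)))
  }
  if (any(num < 0)) return(sprintf("negative value in: %s",
                                   set_label(names(num)[num < 0])))
  if (r$lnr > 1) return("lnr must lie in [0, 1]")
  if (r$lymph_node_count != round(r$lymph_node_count)) {
    return("lymph_node_count must be an integer")
  }
  cats <- list(differentiation = .differentiation_levels,
               histology = .histology_levels, t_stage = .t_levels,
               n_stage = .n_levels, stage_group = .stage_levels)
  for (f in names(cats)) {
    v <- r[[f]]
    if (is.na(v) || !v %in% cats[[f]]) {
      return(sprintf("field %s has invalid value %s", f,
                     if (is.na(v)) "NA" else dQuote(v, q = FALSE)))
    }
  }
  if (is.na(r$lvi) || !is.logical(r$lvi)) return("field lvi must be TRUE/FALSE")
  NULL
}

## Accept common truthy/falsy spellings for lymphovascular invasion.
parse_lvi <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "t", "yes", "y")] <- TRUE
  out[v %in% c("0", "false", "f", "no", "n")] <- FALSE
  out
}

#' Parse a delimited table of raw patient records
#'
#' Reads a CSV of raw clinical attributes (one row per patient) and validates
#' every field: categorical fields must take one of their enumerated values,
#' numeric fields must be non-negative (LNR within \[0, 1\]), ids must be
#' unique, and missing values are rejected — the downstream coding assumes
#' complete one-hot rows.
#'
#' @param file path to a CSV file, or a character scalar containing the CSV
#'   text itself (recognized by embedded newlines).
#' @param col_map optional named character vector mapping canonical field
#'   names (`patient_id`, `age`, `differentiation`, `histology`,
#'   `lymph_node_count`, `cea`, `ca199`, `lvi`, `lnr`, `t_stage`, `n_stage`,
#'   `stage_group`) to the file's column names.
#' @param sep field separator, default ",".
#' @return a data.frame with the canonical columns, one row per patient, in
#'   file order.
#' @examples
#' csv <- paste("patient_id,age,differentiation,histology,lymph_node_count,",
#'   "cea,ca199,lvi,lnr,t_stage,n_stage,stage_group", sep = "")
#' csv <- paste(csv,
#'   "p1,75,poor,mucinous_adenocarcinoma,8,9,20,no,0.4,T4,N2,IIIC",
#'   sep = "\n")
#' parse_patient_table(csv)
#' @export
parse_patient_table <- function(file, col_map = NULL, sep = ",") {
  src <- if (length(file) == 1 && !grepl("\n", file)) {
    if (!file.exists(file)) stop_format(sprintf("file not found: %s", file))
    file
  } else textConnection(paste(file, collapse = "\n"))
  df <- utils::read.csv(src, sep = sep, stringsAsFactors = FALSE,
                        check.names = FALSE, strip.white = TRUE)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), .patient_fields)
    if (length(bad)) stop_validation(sprintf("col_map has unknown field(s): %s",
                                             set_label(bad)))
    hit <- match(col_map, names(df))
    if (anyNA(hit)) {
      stop_format(sprintf("mapped column(s) absent from table: %s",
                          set_label(col_map[is.na(hit)])))
    }
    names(df)[hit] <- names(col_map)
  }
  miss <- setdiff(.patient_fields, names(df))
  if (length(miss)) stop_format(sprintf("missing required column(s): %s",
                                        set_label(miss)))
  df <- df[.patient_fields]
  if (nrow(df) == 0) return(df)
  df$patient_id <- as.character(df$patient_id)
  for (f in c("age", "cea", "ca199", "lnr", "lymph_node_count")) {
    v <- suppressWarnings(as.numeric(df[[f]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop_format(sprintf("row %d, column %s: cannot parse %s as a number",
                          bad[1], f, dQuote(as.character(df[[f]][bad[1]]), q = FALSE)))
    }
    df[[f]] <- v
  }
  df$lvi <- parse_lvi(df$lvi)
  bad <- which(is.na(df$lvi))
  if (length(bad)) stop_format(sprintf("row %d, column lvi: unrecognized value", bad[1]))
  for (f in c("differentiation", "histology", "t_stage", "n_stage", "stage_group")) {
    df[[f]] <- trimws(as.character(df[[f]]))
  }
  validate_patient_records(df)
  df
}

#' Validate a table of raw patient records
#'
#' @param records data.frame with the canonical patient columns.
#' @return `records`, invisibly, or a classed validation error naming the
#'   first offending row and field.
#' @export
validate_patient_records <- function(records) {
  miss <- setdiff(.patient_fields, names(records))
  if (length(miss)) stop_validation(sprintf("missing required column(s): %s",
                                            set_label(miss)))
  dup <- unique(records$patient_id[duplicated(records$patient_id)])
  if (length(dup)) stop_validation(sprintf("duplicate patient id(s): %s",
                                           set_label(dup)))
  for (i in seq_len(nrow(records))) {
    msg <- check_record_fields(as.list(records[i, ]))
    if (!is.null(msg)) stop_validation(sprintf("row %d (id %s): %s", i,
                                               records$patient_id[i], msg))
  }
  invisible(records)
}

#' Binarize one patient record
#'
#' Applies the coding scheme to a single record, producing a 0/1 vector over
#' the 32 canonical attributes with exactly one attribute set per group
#' (the vector always sums to 11).
#'
#' @param record a one-row data.frame or named list with the canonical
#'   patient fields.
#' @param scheme a [crc_coding_scheme()].
#' @return named integer vector of 0/1 over the scheme's attributes.
#' @examples
#' rec <- list(patient_id = "p1", age = 75, differentiation = "poor",
#'   histology = "mucinous_adenocarcinoma", lymph_node_count = 8, cea = 9,
#'   ca199 = 20, lvi = FALSE, lnr = 0.4, t_stage = "T4", n_stage = "N2",
#'   stage_group = "IIIC")
#' binarize_record(rec)
#' @export
binarize_record <- function(record, scheme = crc_coding_scheme()) {
  r <- as.list(record)
  msg <- check_record_fields(r)
  if (!is.null(msg)) stop_validation(sprintf("record %s: %s",
                                             r$patient_id %||% "?", msg))
  out <- integer(0)
  for (g in scheme$groups) {
    k <- g$code(r)
    if (is.na(k) || k < 1 || k > length(g$attributes)) {
      stop_coding(sprintf("record %s: no %s attribute matches", r$patient_id, g$name))
    }
    v <- integer(length(g$attributes))
    v[k] <- 1L
    names(v) <- g$attributes
    out <- c(out, v)
  }
  out
}

#' Binarize many records into a 0/1 matrix
#'
#' @param records data.frame of raw patient records (see
#'   [parse_patient_table()]).
#' @inheritParams binarize_record
#' @return integer matrix, one row per patient (row names = patient ids),
#'   columns = the scheme's 32 attributes.
#' @export
binarize_records <- function(records, scheme = crc_coding_scheme()) {
  validate_patient_records(records)
  rows <- lapply(seq_len(nrow(records)),
                 function(i) binarize_record(as.list(records[i, ]), scheme))
  m <- do.call(rbind, rows)
  rownames(m) <- records$patient_id
  m
}

#' Build a formal context from raw patient records
#'
#' Binarizes every record and assembles the objects-by-attributes incidence
#' matrix: objects are patient ids in input order, attributes are the
#' scheme's 32 names in canonical order.
#'
#' @inheritParams binarize_records
#' @return a [formal_context()].
#' @export
build_context <- function(records, scheme = crc_coding_scheme()) {
  if (is.null(records) || nrow(records) == 0) {
    stop_validation("cannot build a context from zero records")
  }
  formal_context(binarize_records(records, scheme))
}
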