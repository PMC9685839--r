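## Small worked-example objects used in documentation, tests and the
## acceptance checks. Built in code so they are always available.

#' Demo context: 3 patients, 7 binary attributes
#'
#' The miniature formal context used throughout the documentation: three
#' colorectal-cancer patients described by age band, examined-lymph-node
#' band and CEA band. Its concept lattice has 7 concepts, 5 of them with
#' nonempty extent and intent.
#'
#' @return a [formal_context()] with objects P1-P3 and attributes `Age_L`,
#'   `Age_M`, `Age_H`, `Lym_L`, `Lym_H`, `CEA_L`, `CEA_H`.
#' @examples
#' ctx <- crc_demo_context()
#' proper_concept_count(concept_lattice(ctx))
#' @export
crc_demo_context <- function() {
  rows <- c(P1 = "0011001", P2 = "0100110", P3 = "0100101")
  I <- do.call(rbind, lapply(rows, function(r) as.numeric(strsplit(r, "")[[1]])))
  formal_context(I, objects = names(rows),
                 attributes = c("Age_L", "Age_M", "Age_H", "Lym_L", "Lym_H",
                                "CEA_L", "CEA_H"))
}

## (id, objects, intent) for the ten-concept knowledge-base excerpt around
## reference patient 980; intents over the 32-attribute clinical space.
.demo_kb_rows <- list(
  list("C31739", "980",
       c("Age_L", "Degre_L", "MAd", "T2", "N0", "Lym_L", "CEA_L", "Ca199_L", "Lv_N", "LNR_L", "I")),
  list("C31719", "2425",
       c("Age_L", "Degre_L", "MAd", "T4", "N0", "Lym_L", "CEA_L", "Ca199_L", "Lv_N", "LNR_L", "IIB")),
  list("C31740", "772",
       c("Age_L", "Degre_L", "MAd", "T1", "N0", "Lym_H", "CEA_L", "Ca199_L", "Lv_N", "LNR_L", "I")),
  list("C31718", c("436", "474", "725", "759", "1074", "1146", "1761", "2248"),
       c("Age_L", "Degre_L", "MAd", "T4", "N0", "Lym_H", "CEA_L", "Ca199_L", "Lv_N", "LNR_L", "IIB")),
  list("C31738", c("411", "569"),
       c("Age_L", "Degre_L", "MAd", "T3", "N0", "Lym_H", "CEA_L", "Ca199_L", "Lv_N", "LNR_L", "IIA")),
  list("C31728", c("411", "569", "2279"),
       c("Age_L", "Degre_L", "MAd", "T3", "Lym_H", "CEA_L", "Ca199_L", "Lv_N", "LNR_L")),
  list("C31732", "2279",
       c("Age_L", "Degre_L", "MAd", "T3", "N1", "Lym_H", "CEA_L", "Ca199_L", "Lv_N", "LNR_L", "IIIB")),
  list("C31734", c("411", "549", "569", "831"),
       c("Age_L", "Degre_L", "MAd", "T3", "N0", "Lym_H", "Ca199_L", "Lv_N", "LNR_L", "IIA")),
  list("C31737", c("549", "831"),
       c("Age_L", "Degre_L", "MAd", "T3", "N0", "Lym_H", "CEA_H", "Ca199_L", "Lv_N", "LNR_L", "IIA")),
  list("C31723", c("411", "549", "569", "831", "2279"),
       c("Age_L", "Degre_L", "MAd", "T3", "Lym_H", "Ca199_L", "Lv_N", "LNR_L"))
)

#' Demo knowledge-base excerpt: ten concepts around a reference patient
#'
#' A ten-concept excerpt of a full-cohort colorectal-cancer knowledge base,
#' centered on reference patient 980 (a stage-I patient whose 11 attributes
#' form the intent of the first concept). Used to demonstrate ranked
#' retrieval: querying with [crc_demo_query()] under `alpha = 0, beta = 1`
#' yields the score sequence 1.000, 0.818, 0.818, 0.727, 0.727, 0.636,
#' 0.636, 0.636, 0.636, 0.545.
#'
#' @return list of ten [formal_concept()]s.
#' @examples
#' retrieve_similar(crc_demo_kb(), crc_demo_query(), top_k = 10)
#' @export
crc_demo_kb <- function() {
  lapply(.demo_kb_rows, function(r) formal_concept(r[[2]], r[[3]], id = r[[1]]))
}

#' @rdname crc_demo_kb
#' @return `crc_demo_query()` returns the reference patient's 11 binary
#'   attributes (a character vector), suitable as a retrieval query.
#' @export
crc_demo_query <- function() {
  c("Age_L", "Degre_L", "MAd", "T2", "N0", "Lym_L", "CEA_L", "Ca199_L",
    "Lv_N", "LNR_L", "I")
}
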