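## Seeded synthetic colorectal-cancer cohorts.
##
## The generator emulates the marginal category frequencies of the 2442-
## patient hospital cohort the knowledge base was built from (that dataset
## is not publicly deposited). Categories are drawn per attribute group;
## continuous values are then drawn uniformly inside the selected bin, which
## is sufficient because the coding step only ever sees the bin.

.marginal_defaults <- list(
  age = list(field = "age",
             categories = c("<60", "60-70", ">=70"),
             counts = c(1108, 824, 510)),
  differentiation = list(field = "differentiation",
                         categories = c("moderate", "poor", "well"),
                         counts = c(425, 1878, 139)),
  histology = list(field = "histology",
                   categories = c("mucinous_adenocarcinoma", "adenocarcinoma"),
                   counts = c(327, 2115)),
  lymph_nodes = list(field = "lymph_node_count",
                     categories = c("<10", ">=10"),
                     counts = c(224, 2218)),
  cea = list(field = "cea", categories = c("<5", ">=5"),
             counts = c(1487, 955)),
  ca199 = list(field = "ca199", categories = c("<37", ">=37"),
               counts = c(2100, 342)),
  lvi = list(field = "lvi", categories = c("yes", "no"),
             counts = c(109, 2333)),
  lnr = list(field = "lnr", categories = c("<0.13", ">=0.13"),
             counts = c(1779, 663)),
  t_stage = list(field = "t_stage", categories = c("T1", "T2", "T3", "T4"),
                 counts = c(128, 388, 592, 1334)),
  n_stage = list(field = "n_stage", categories = c("N0", "N1", "N2"),
                 counts = c(1489, 533, 420)),
  stage_group = list(field = "stage_group",
                     categories = c("I", "IIA", "IIB", "IIC", "IIIA", "IIIB", "IIIC"),
                     counts = c(428, 396, 648, 17, 66, 530, 357))
)

#' Default cohort marginal frequencies
#'
#' The per-group category probabilities used by [generate_cohort()], taken
#' from the published baseline table of the 2442-patient reference cohort
#' (probabilities are category counts / 2442, so each group sums to 1
#' exactly).
#'
#' @return an object of class `cohort_marginals`: a named list of groups,
#'   each with `field`, `categories` and `prob`.
#' @export
crc_cohort_marginals <- function() {
  groups <- lapply(.marginal_defaults, function(g) {
    list(field = g$field, categories = g$categories,
         prob = g$counts / sum(g$counts))
  })
  structure(groups, class = "cohort_marginals")
}

#' @export
print.cohort_marginals <- function(x, ...) {
  cat(sprintf("Cohort marginals: %d attribute groups\n", length(x)))
  for (nm in names(x)) {
    g <- x[[nm]]
    cat(sprintf("  %-16s %s\n", nm,
                paste(sprintf("%s=%.3f", g$categories, g$prob), collapse = " ")))
  }
  invisible(x)
}

validate_marginals <- function(marginals) {
  for (nm in names(marginals)) {
    g <- marginals[[nm]]
    if (anyNA(g$prob) || any(g$prob < 0) || abs(sum(g$prob) - 1) > 1e-9) {
      stop_validation(sprintf("group %s: probabilities must be non-negative and sum to 1", nm))
    }
    if (length(g$prob) != length(g$categories)) {
      stop_validation(sprintf("group %s: one probability per category required", nm))
    }
  }
  invisible(marginals)
}

## Draw a raw value uniformly inside a category's bin.
draw_in_bin <- function(group, category, u) {
  switch(paste(group, category, sep = ":"),
    "age:<60" = 18 + u * (60 - 18),
    "age:60-70" = 60 + u * 10,
    "age:>=70" = 70 + u * 25,
    "lymph_nodes:<10" = 1 + floor(u * 9),      # integer in [1, 9]
    "lymph_nodes:>=10" = 10 + floor(u * 51),   # integer in [10, 60]
    "cea:<5" = u * 5,
    "cea:>=5" = 5 + u * 95,
    "ca199:<37" = u * 37,
    "ca199:>=37" = 37 + u * 463,
    "lnr:<0.13" = u * 0.13,
    "lnr:>=0.13" = 0.13 + u * 0.87,
    category   # categorical groups pass their label through
  )
}

## AJCC-like stage lookup for tnm_consistent mode. An approximation of how
## real cohorts couple stage group with T and N, not a claim about the
## reference dataset: T1-2/N0 -> I; T3/N0 -> IIA; T4/N0 -> IIB or IIC
## (sub-draw at the marginal IIB:IIC odds); N1 -> IIIA if T1-2 else IIIB;
## N2 -> IIIC.
stage_from_tn <- function(t_stage, n_stage, u) {
  if (n_stage == "N2") return("IIIC")
  if (n_stage == "N1") {
    return(if (t_stage %in% c("T1", "T2")) "IIIA" else "IIIB")
  }
  if (t_stage %in% c("T1", "T2")) return("I")
  if (t_stage == "T3") return("IIA")
  if (u < 648 / (648 + 17)) "IIB" else "IIC"
}

#' Generate a synthetic patient cohort
#'
#' Draws `n` complete patient records with each attribute group sampled from
#' its marginal distribution. `mode = "independent"` samples every group —
#' including stage — independently (the reference cohort is published only
#' as marginals); `mode = "tnm_consistent"` instead derives the stage group
#' from the drawn T and N categories via a fixed AJCC-like lookup. Output is
#' fully reproducible from `seed`.
#'
#' @param n number of patients (>= 0).
#' @param marginals a [crc_cohort_marginals()]-shaped object.
#' @param seed integer seed; the generator uses a private RNG stream.
#' @param mode `"independent"` or `"tnm_consistent"`.
#' @return data.frame of raw patient records (ids `p1`, `p2`, ...), valid
#'   per [validate_patient_records()].
#' @examples
#' cohort <- generate_cohort(100, seed = 1)
#' table(cohort$stage_group)
#' @export
generate_cohort <- function(n, marginals = crc_cohort_marginals(), seed = 1,
                            mode = c("independent", "tnm_consistent")) {
  mode <- match.arg(mode)
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != round(n)) {
    stop_validation("n must be a non-negative integer")
  }
  n <- as.integer(n)
  validate_marginals(marginals)
  cols <- list(patient_id = if (n) paste0("p", seq_len(n)) else character(0))
  with_seed(seed, {
    raw <- list()
    for (nm in names(marginals)) {
      g <- marginals[[nm]]
      cat_draw <- if (n) sample(g$categories, n, replace = TRUE, prob = g$prob) else character(0)
      u <- stats::runif(n)
      raw[[nm]] <- if (n) {
        vapply(seq_len(n), function(i) as.character(draw_in_bin(nm, cat_draw[i], u[i])), "")
      } else character(0)
    }
    if (mode == "tnm_consistent" && n) {
      us <- stats::runif(n)
      raw$stage_group <- vapply(seq_len(n), function(i) {
        stage_from_tn(raw$t_stage[i], raw$n_stage[i], us[i])
      }, "")
    }
  })
  numeric_fields <- c(age = "age", lymph_nodes = "lymph_node_count",
                      cea = "cea", ca199 = "ca199", lnr = "lnr")
  for (nm in names(marginals)) {
    field <- marginals[[nm]]$field
    v <- raw[[nm]]
    cols[[field]] <- if (nm %in% names(numeric_fields)) as.numeric(v)
    else if (nm == "lvi") v == "yes"
    else v
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  df[c(.patient_fields)]
}

#' Compare a cohort's category frequencies to target marginals
#'
#' Summarizes the cohort in the shape of the published baseline table:
#' observed and expected counts and proportions per category, with the
#' largest absolute proportion deviation as an attribute for quick checks.
#'
#' @param cohort nonempty data.frame of raw patient records.
#' @param marginals target marginals (default [crc_cohort_marginals()]).
#' @return data.frame with columns `group`, `category`, `observed`,
#'   `expected`, `obs_prop`, `target_prop`, `deviation`; attribute
#'   `max_abs_deviation`.
#' @export
marginal_report <- function(cohort, marginals = crc_cohort_marginals()) {
  if (is.null(cohort) || nrow(cohort) == 0) {
    stop_validation("cohort is empty")
  }
  validate_marginals(marginals)
  n <- nrow(cohort)
  scheme_bins <- list(
    age = function(x) ifelse(x < 60, "<60", ifelse(x < 70, "60-70", ">=70")),
    lymph_nodes = function(x) ifelse(x < 10, "<10", ">=10"),
    cea = function(x) ifelse(x < 5, "<5", ">=5"),
    ca199 = function(x) ifelse(x < 37, "<37", ">=37"),
    lnr = function(x) ifelse(x < 0.13, "<0.13", ">=0.13"),
    lvi = function(x) ifelse(x, "yes", "no")
  )
  rows <- list()
  for (nm in names(marginals)) {
    g <- marginals[[nm]]
    v <- cohort[[g$field]]
    cat_obs <- if (nm %in% names(scheme_bins)) scheme_bins[[nm]](v) else as.character(v)
    obs <- vapply(g$categories, function(cc) sum(cat_obs == cc), 0L)
    rows[[nm]] <- data.frame(group = nm, category = g$categories,
                             observed = as.integer(obs),
                             expected = n * g$prob,
                             obs_prop = obs / n, target_prop = g$prob,
                             deviation = obs / n - g$prob,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "max_abs_deviation") <- max(abs(out$deviation))
  out
}
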