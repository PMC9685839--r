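# Fixtures are built in code; no binary data.

random_context <- function(n_obj, n_att, seed, p = 0.4) {
  set.seed(seed)
  I <- matrix(stats::rbinom(n_obj * n_att, 1, p), n_obj, n_att)
  formal_context(I, paste0("g", seq_len(n_obj)), paste0("m", seq_len(n_att)))
}

# A valid raw record drawn uniformly over the whole attribute space,
# occasionally landing exactly on a bin cutoff.
random_record <- function(id = "r1") {
  maybe_cut <- function(x, cuts) {
    if (stats::runif(1) < 0.15) sample(cuts, 1) else x
  }
  list(
    patient_id = id,
    age = maybe_cut(stats::runif(1, 18, 95), c(60, 70)),
    differentiation = sample(c("poor", "moderate", "well"), 1),
    histology = sample(c("mucinous_adenocarcinoma", "adenocarcinoma"), 1),
    lymph_node_count = sample(0:60, 1),
    cea = maybe_cut(stats::runif(1, 0, 100), 5),
    ca199 = maybe_cut(stats::runif(1, 0, 500), 37),
    lvi = sample(c(TRUE, FALSE), 1),
    lnr = maybe_cut(stats::runif(1, 0, 1), 0.13),
    t_stage = sample(c("T1", "T2", "T3", "T4"), 1),
    n_stage = sample(c("N0", "N1", "N2"), 1),
    stage_group = sample(c("I", "IIA", "IIB", "IIC", "IIIA", "IIIB", "IIIC"), 1)
  )
}

# Order-independent fingerprint of a concept set.
concept_keys <- function(concepts) {
  sort(vapply(concepts, function(co) {
    paste(paste(sort(co$extent), collapse = ","),
          paste(sort(co$intent), collapse = ","), sep = " | ")
  }, ""))
}

patients_csv_path <- function() {
  system.file("extdata", "synthetic_patients.csv", package = "fcakb")
}

# TRUE iff intent mask a precedes mask b in the lectic order (attribute 1
# most significant): at the first position where they differ, b has the
# attribute.
lectic_lt <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && b[d[1]]
}
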