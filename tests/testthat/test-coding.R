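test_that("patient tables parse faithfully and in row order", {
  df <- parse_patient_table(patients_csv_path())
  expect_equal(nrow(df), 5)
  expect_equal(df$patient_id, paste0("p", 1:5))
  expect_equal(df$age[1], 75)
  expect_equal(df$differentiation[1], "poor")
  expect_equal(df$histology[1], "mucinous_adenocarcinoma")
  expect_equal(df$lymph_node_count[1], 8)
  expect_false(df$lvi[1])
  expect_true(df$lvi[3])
  expect_equal(df$stage_group, c("IIIC", "I", "IIIB", "I", "IIA"))
})

test_that("empty table with a valid header parses to zero records", {
  hdr <- paste(readLines(patients_csv_path(), n = 1), collapse = "")
  df <- parse_patient_table(paste0(hdr, "\n"))
  expect_equal(nrow(df), 0)
})

test_that("parser rejects malformed tables with row-level messages", {
  lines <- readLines(patients_csv_path())
  dup <- paste(c(lines, sub("^p5", "p1", lines[6])), collapse = "\n")
  expect_error(parse_patient_table(dup), "duplicate patient id",
               class = "fcakb_validation_error")
  bad_cell <- lines
  bad_cell[2] <- sub(",9\\.0,", ",,", bad_cell[2])
  expect_error(parse_patient_table(paste(bad_cell, collapse = "\n")),
               "row 1, column cea", class = "fcakb_format_error")
  no_col <- sub("cea,", "x,", paste(lines, collapse = "\n"))
  expect_error(parse_patient_table(no_col), "missing required column",
               class = "fcakb_format_error")
  bad_cat <- lines
  bad_cat[3] <- sub("T2", "T9", bad_cat[3])
  expect_error(parse_patient_table(paste(bad_cat, collapse = "\n")),
               "row 2.*t_stage", class = "fcakb_validation_error")
})

test_that("column mapping renames external headers", {
  lines <- readLines(patients_csv_path())
  lines[1] <- sub("^patient_id", "id", lines[1])
  df <- parse_patient_table(paste(lines, collapse = "\n"),
                            col_map = c(patient_id = "id"))
  expect_equal(df$patient_id[1], "p1")
})

test_that("the reference record reproduces its printed 32-bit coding", {
  rec <- list(patient_id = "Patient1", age = 75, differentiation = "poor",
              histology = "mucinous_adenocarcinoma", lymph_node_count = 8,
              cea = 9, ca199 = 20, lvi = FALSE, lnr = 0.4,
              t_stage = "T4", n_stage = "N2", stage_group = "IIIC")
  v <- binarize_record(rec)
  expect_equal(paste(v, collapse = ""),
               paste0("0011001000010011", "0011010010000001"))
  # any raw values inside the same bins give the identical vector
  rec2 <- within(rec, { age <- 71; cea <- 5; ca199 <- 36.9; lnr <- 0.13
                        lymph_node_count <- 9 })
  expect_equal(binarize_record(rec2), v)
})

test_that("bin cutoffs fall in the upper bin", {
  base <- random_record("b")
  at <- function(field, value) {
    r <- base; r[[field]] <- value
    v <- binarize_record(r)
    names(v)[v == 1]
  }
  expect_true("Age_M" %in% at("age", 60))
  expect_true("Age_L" %in% at("age", 59.99))
  expect_true("Age_H" %in% at("age", 70))
  expect_true("CEA_H" %in% at("cea", 5))
  expect_true("CEA_L" %in% at("cea", 4.999))
  expect_true("Ca199_H" %in% at("ca199", 37))
  expect_true("LNR_H" %in% at("lnr", 0.13))
  expect_true("LNR_L" %in% at("lnr", 0.1299))
  expect_true("Lym_H" %in% at("lymph_node_count", 10))
  expect_true("Lym_L" %in% at("lymph_node_count", 9))
})

test_that("one-hot conservation: every coded row sums to 11, one per group", {
  scheme <- crc_coding_scheme()
  group_sizes <- lengths(lapply(scheme$groups, `[[`, "attributes"))
  set.seed(7)
  for (i in 1:300) {
    v <- binarize_record(random_record(paste0("r", i)), scheme)
    expect_equal(sum(v), 11)
    offsets <- cumsum(c(0, group_sizes[-length(group_sizes)]))
    per_group <- vapply(seq_along(group_sizes), function(g) {
      sum(v[offsets[g] + seq_len(group_sizes[g])])
    }, 0L)
    expect_true(all(per_group == 1L))
  }
})

test_that("binarization is deterministic", {
  set.seed(11)
  rec <- random_record("d")
  expect_identical(binarize_record(rec), binarize_record(rec))
})

test_that("build_context assembles ids, canonical attributes and row sums", {
  df <- parse_patient_table(patients_csv_path())
  ctx <- build_context(df)
  expect_s3_class(ctx, "formal_context")
  expect_equal(ctx$objects, df$patient_id)
  expect_equal(ctx$attributes, scheme_attributes(crc_coding_scheme()))
  expect_equal(length(ctx$attributes), 32)
  expect_true(all(rowSums(ctx$incidence) == 11))
  one <- build_context(df[1, ])
  expect_equal(dim(one), c(1L, 32L))
  expect_error(build_context(df[0, ]), class = "fcakb_validation_error")
})
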