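test_that("protein-change strings parse to (ref, position, alt)", {
  expect_equal(parse_protein_change("p.E207D"),
               data.frame(ref_aa = "E", position = 207L, alt_aa = "D"))
  expect_equal(parse_protein_change("p.K31A")$position, 31L)
  expect_error(parse_protein_change("E207"), "malformed")
  expect_error(parse_protein_change("p.E207"), "malformed")
  expect_error(parse_protein_change(""), "empty")
})

mixed_tab <- data.frame(
  patient_id = sprintf("P%d", 1:4),
  gene = c("TRPM8", "TRPM8", "RAP1A", "TRPM8"),
  variant_class = c("Missense_Mutation", "Nonsense_Mutation",
                    "Missense_Mutation", "Silent"),
  protein_change = c("p.E207D", "p.Q100*", "p.K31A", "p.L50L"),
  stringsAsFactors = FALSE)

test_that("missense filtering keeps only point missense records", {
  kept <- filter_missense(mixed_tab)
  expect_equal(nrow(kept), 2)
  expect_equal(attr(kept, "n_missense"), 2)
  expect_equal(nrow(filter_missense(mixed_tab[0, ])), 0)
  expect_warning(filter_missense(mixed_tab[mixed_tab$variant_class == "Silent", ]),
                 "no missense")
})

test_that("codon watch-list filtering matches gene and parsed position", {
  hit <- mutations_at_codons(mixed_tab, "TRPM8", c(207, 240))
  expect_equal(nrow(hit), 1)
  expect_equal(hit$position, 207L)
  hit2 <- mutations_at_codons(mixed_tab, "RAP1A", c(31, 32))
  expect_equal(hit2$position, 31L)  # p.K31A sits on a watched codon
  # watched codons with no entries in the table give an empty result
  expect_equal(nrow(mutations_at_codons(mixed_tab, "RAP1A", c(99, 100))), 0)
  expect_error(mutations_at_codons(mixed_tab, "TRPM8", integer(0)), "non-empty")
  expect_error(mutations_at_codons(mixed_tab, "TRPM8", c(0, 207)), ">= 1")
})

test_that("mutational burden normalises by cohort size and megaresidues", {
  expect_equal(attr(mutational_burden(26, 10182, 184), "display"), "13.88")
  expect_equal(attr(mutational_burden(203, 10182, 1104), "display"), "18.06")
  expect_equal(as.numeric(mutational_burden(0, 100, 500)), 0)
  expect_error(mutational_burden(5, 0, 100), "n_patients")
  expect_error(mutational_burden(5, 10, 0), "protein_length")

  # linear in the count; halving the cohort doubles the burden
  set.seed(1)
  for (i in 1:20) {
    n <- sample(1:500, 1); pts <- sample(2:2000, 1) * 2; len <- sample(50:2000, 1)
    mb <- as.numeric(mutational_burden(n, pts, len))
    expect_equal(as.numeric(mutational_burden(3 * n, pts, len)), 3 * mb)
    expect_equal(as.numeric(mutational_burden(n, pts / 2, len)), 2 * mb)
  }
})

test_that("cohort_burden counts missense per gene from a mutation table", {
  tab <- cohort_burden(mixed_tab, n_patients = 10,
                       gene_lengths = c(TRPM8 = 1104, RAP1A = 184))
  expect_equal(tab$n_mutations, c(1L, 1L))
  expect_equal(tab$mb[tab$gene == "RAP1A"], 1 / (10 * 184e-6))
})

test_that("labeling follows the rule precedence and is a total function", {
  mk <- function(cohort, m = NA, stage = NA, figo = NA)
    data.frame(sample_id = "s", source_cohort = cohort, ajcc_m = m,
               ajcc_stage = stage, figo_stage = figo, stringsAsFactors = FALSE)
  expect_equal(label_sample(mk("GTEx"))$label, "healthy")
  # GTEx precedence holds even with stray staging entries
  expect_equal(label_sample(mk("GTEx", m = "M1"))$label, "healthy")
  expect_equal(label_sample(mk("TCGA", m = "M1"))$label, "metastatic")
  expect_equal(label_sample(mk("TCGA", m = "M1a"))$label, "metastatic")
  expect_equal(label_sample(mk("TCGA", m = "M0"))$label, "not_metastatic")
  expect_equal(label_sample(mk("TCGA", stage = "Stage IV"))$label, "metastatic")
  expect_equal(label_sample(mk("TCGA", stage = "stage ivb"))$label, "metastatic")
  expect_equal(label_sample(mk("TCGA", stage = "Stage II"))$label, "not_metastatic")
  expect_equal(label_sample(mk("TCGA", figo = "III"))$label, "metastatic")
  expect_equal(label_sample(mk("TCGA", figo = "IV"))$label, "metastatic")
  expect_equal(label_sample(mk("TCGA", figo = "I"))$label, "not_metastatic")
  expect_equal(label_sample(mk("TCGA"))$label, "not_metastatic")
  expect_error(label_sample(mk("ICGC")), "unknown source_cohort")

  # exhaustive rule-combination table: every row gets exactly one label/rule
  combos <- expand.grid(source_cohort = c("TCGA", "GTEx"),
                        ajcc_m = c(NA, "M0", "M1"),
                        ajcc_stage = c(NA, "Stage II", "Stage IV"),
                        figo_stage = c(NA, "I", "III", "IV"),
                        stringsAsFactors = FALSE)
  combos$sample_id <- sprintf("c%03d", seq_len(nrow(combos)))
  lab <- label_sample(combos)
  expect_equal(nrow(lab), nrow(combos))
  expect_true(all(lab$label %in% c("healthy", "metastatic", "not_metastatic")))
  expect_true(all(lab$label[combos$source_cohort == "GTEx"] == "healthy"))
  tcga <- combos$source_cohort == "TCGA"
  should_meta <- tcga & ((!is.na(combos$ajcc_m) & combos$ajcc_m == "M1") |
                         (!is.na(combos$ajcc_stage) & combos$ajcc_stage == "Stage IV") |
                         (!is.na(combos$figo_stage) & combos$figo_stage %in% c("III", "IV")))
  expect_equal(lab$label == "metastatic", unname(should_meta))
})

test_that("cohort assembly routes by tissue/project and drops TARGET", {
  meta <- data.frame(
    sample_id = sprintf("s%d", 1:7),
    source_cohort = c("GTEx", "GTEx", "GTEx", "TCGA", "TCGA", "TARGET", "TCGA"),
    project = c(NA, NA, NA, "TCGA-PRAD", "TCGA-UCEC", "TARGET-ALL", "TCGA-LUAD"),
    tissue_label = c("Breast", "Cervix Uteri", "Prostate", NA, NA, NA, NA),
    stringsAsFactors = FALSE)
  out <- suppressMessages(assemble_cohorts(meta))
  expect_equal(out$Breast$sample_id, "s1")
  expect_equal(out$Uterus$sample_id, c("s2", "s5"))
  expect_equal(out$Prostate$sample_id, c("s3", "s4"))
  expect_equal(attr(out, "n_target_dropped"), 1)
  expect_equal(attr(out, "n_unmatched"), 1)  # TCGA-LUAD matches no cohort
  expect_message(assemble_cohorts(meta), "dropped 1 TARGET")
})
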