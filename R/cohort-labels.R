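# Sample labeling and cohort assembly for TCGA/GTEx-style expression
# analyses. Labels: "healthy" (GTEx), "metastatic" (AJCC m-category M1*,
# AJCC stage IV or equivalent, or FIGO stage III/IV), "not metastatic"
# (everything else). The rule precedence follows the source cohort first
# (GTEx rows carry no staging), then the metastasis indicators.

# Default "stage IV or equivalent" encodings; configurable because clinical
# exports differ in how they spell stages.
STAGE_IV_EQUIV <- c("STAGE IV", "IV", "IVA", "IVB", "IVC",
                    "STAGE IVA", "STAGE IVB", "STAGE IVC")
FIGO_META <- c("III", "IIIA", "IIIB", "IIIC", "IIIC1", "IIIC2",
               "IV", "IVA", "IVB",
               "STAGE III", "STAGE IIIA", "STAGE IIIB", "STAGE IIIC",
               "STAGE IV", "STAGE IVA", "STAGE IVB")

norm_stage <- function(x) toupper(trimws(as.character(x)))

#' Label samples as healthy / metastatic / not metastatic
#'
#' Applies the labeling rules in precedence order and reports which rule
#' matched: GTEx samples are `healthy`; TCGA samples are `metastatic` when
#' the AJCC m category indicates metastasis (value starting with `M1`), the
#' AJCC stage is IV or an equivalent encoding, or the FIGO stage is III or
#' IV; all remaining samples are `not_metastatic`. Every valid row receives
#' exactly one label.
#'
#' @param meta metadata data frame with columns `sample_id`,
#'   `source_cohort`, and optionally `ajcc_m`, `ajcc_stage`, `figo_stage`
#'   (missing staging is treated as absent). A single-row data frame or a
#'   list describing one sample is also accepted.
#' @param stage_iv_values,figo_meta_values configurable stage encodings,
#'   matched case-insensitively.
#' @return data frame `sample_id`, `label`, `rule` where `rule` is one of
#'   `gtex`, `ajcc_m`, `ajcc_stage_iv`, `figo_iii_iv`, `fallback`.
#' @examples
#' label_sample(gen_clinical_metadata(1))
#' @export
label_sample <- function(meta, stage_iv_values = STAGE_IV_EQUIV,
                         figo_meta_values = FIGO_META) {
  if (!is.data.frame(meta)) meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  for (col in c("ajcc_m", "ajcc_stage", "figo_stage"))
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
  bad <- !meta$source_cohort %in% c("TCGA", "GTEx", "TARGET")
  if (any(bad))
    stop("unknown source_cohort: ",
         paste(unique(meta$source_cohort[bad]), collapse = ", "),
         call. = FALSE)
  n <- nrow(meta)
  label <- rep("not_metastatic", n)
  rule <- rep("fallback", n)
  m_meta <- !is.na(meta$ajcc_m) & startsWith(toupper(trimws(meta$ajcc_m)), "M1")
  s_iv <- !is.na(meta$ajcc_stage) &
    norm_stage(meta$ajcc_stage) %in% toupper(stage_iv_values)
  figo <- !is.na(meta$figo_stage) &
    norm_stage(meta$figo_stage) %in% toupper(figo_meta_values)
  hit <- figo;  label[hit] <- "metastatic"; rule[hit] <- "figo_iii_iv"
  hit <- s_iv;  label[hit] <- "metastatic"; rule[hit] <- "ajcc_stage_iv"
  hit <- m_meta; label[hit] <- "metastatic"; rule[hit] <- "ajcc_m"
  gtex <- meta$source_cohort == "GTEx"
  label[gtex] <- "healthy"; rule[gtex] <- "gtex"
  data.frame(sample_id = meta$sample_id, label = label, rule = rule,
             stringsAsFactors = FALSE)
}

#' Assemble tissue cohorts from mixed TCGA/GTEx/TARGET metadata
#'
#' Routes samples into the Breast, Prostate and Uterus datasets: GTEx
#' samples by tissue label (`Breast`; `Prostate`; `Uterus` or
#' `Cervix Uteri`), TCGA samples by project (`TCGA-BRCA`; `TCGA-PRAD`;
#' `TCGA-UCEC`). TARGET samples are removed, and samples matching no cohort
#' are excluded; both counts are reported via a message.
#'
#' @param meta metadata data frame (see [gen_clinical_metadata()]).
#' @return named list of data frames `Breast`, `Prostate`, `Uterus`, with
#'   attributes `n_target_dropped` and `n_unmatched`.
#' @export
assemble_cohorts <- function(meta) {
  validate_metadata(meta)
  is_target <- meta$source_cohort == "TARGET"
  n_target <- sum(is_target)
  meta <- meta[!is_target, , drop = FALSE]
  gtex <- meta$source_cohort == "GTEx"
  tissue <- ifelse(is.na(meta$tissue_label), "", meta$tissue_label)
  project <- if (is.null(meta$project)) rep(NA_character_, nrow(meta)) else meta$project
  project <- ifelse(is.na(project), "", project)
  cohort <- rep(NA_character_, nrow(meta))
  cohort[gtex & tissue == "Breast"] <- "Breast"
  cohort[gtex & tissue == "Prostate"] <- "Prostate"
  cohort[gtex & tissue %in% c("Uterus", "Cervix Uteri")] <- "Uterus"
  cohort[!gtex & project == "TCGA-BRCA"] <- "Breast"
  cohort[!gtex & project == "TCGA-PRAD"] <- "Prostate"
  cohort[!gtex & project == "TCGA-UCEC"] <- "Uterus"
  n_unmatched <- sum(is.na(cohort))
  if (n_target > 0 || n_unmatched > 0)
    message(sprintf("assemble_cohorts: dropped %d TARGET and %d unmatched sample(s)",
                    n_target, n_unmatched))
  out <- lapply(c(Breast = "Breast", Prostate = "Prostate", Uterus = "Uterus"),
                function(co) {
                  df <- meta[!is.na(cohort) & cohort == co, , drop = FALSE]
                  rownames(df) <- NULL
                  df
                })
  attr(out, "n_target_dropped") <- n_target
  attr(out, "n_unmatched") <- n_unmatched
  out
}
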