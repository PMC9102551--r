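# Somatic mutation tables: HGVS-short protein-change parsing, missense
# filtering, codon watch-lists, and the mutational-burden statistic
# (mutations per patient per megaresidue).

#' Parse an HGVS-like short protein-change string
#'
#' Accepts `"p.<ref><pos><alt>"` with 1-letter amino-acid codes, e.g.
#' `"p.E207D"`.
#'
#' @param text character vector of protein-change strings.
#' @return data frame `ref_aa`, `position`, `alt_aa` (one row per input).
#' @examples
#' parse_protein_change("p.E207D")
#' @export
parse_protein_change <- function(text) {
  if (length(text) == 0 || any(is.na(text) | text == ""))
    stop("empty protein-change string", call. = FALSE)
  m <- regexec("^p\\.([A-Z])([0-9]+)([A-Z*])$", text)
  parts <- regmatches(text, m)
  bad <- lengths(parts) != 4
  if (any(bad))
    stop("malformed protein change: ", paste(text[bad], collapse = ", "),
         call. = FALSE)
  out <- do.call(rbind, parts)
  data.frame(ref_aa = out[, 2], position = as.integer(out[, 3]),
             alt_aa = out[, 4], stringsAsFactors = FALSE)
}

#' Keep only point missense mutations
#'
#' @param records mutation data frame with a `variant_class` column.
#' @param missense_classes variant-class values counted as point missense.
#' @return the missense subset; attribute `n_missense` carries the count.
#'   Warns when a non-empty input has no missense records.
#' @export
filter_missense <- function(records,
                            missense_classes = c("Missense_Mutation",
                                                 "missense_variant")) {
  stopifnot(is.data.frame(records), "variant_class" %in% names(records))
  out <- records[records$variant_class %in% missense_classes, , drop = FALSE]
  if (nrow(records) > 0 && nrow(out) == 0)
    warning("no missense mutations in table", call. = FALSE)
  rownames(out) <- NULL
  attr(out, "n_missense") <- nrow(out)
  out
}

#' Mutations hitting a set of watched codons of a gene
#'
#' @param records mutation data frame (`gene`, `protein_change`).
#' @param gene gene symbol to filter on.
#' @param positions non-empty set of 1-based codon positions (all >= 1).
#' @return the matching records, with parsed `ref_aa`, `position`, `alt_aa`
#'   columns appended.
#' @export
mutations_at_codons <- function(records, gene, positions) {
  if (length(positions) == 0) stop("`positions` must be non-empty", call. = FALSE)
  if (any(positions < 1)) stop("codon positions must be >= 1", call. = FALSE)
  sub <- records[records$gene == gene, , drop = FALSE]
  if (nrow(sub) == 0) {
    sub$ref_aa <- character(0); sub$position <- integer(0)
    sub$alt_aa <- character(0)
    return(sub)
  }
  parsed <- parse_protein_change(sub$protein_change)
  sub <- cbind(sub, parsed)
  sub <- sub[sub$position %in% positions, , drop = FALSE]
  rownames(sub) <- NULL
  sub
}

#' Mutational burden: mutations per patient per megaresidue
#'
#' `mb = n_mutations / (n_patients * protein_length_aa * 1e-6)` — the
#' cohort-wide mutation count of a gene normalised by cohort size and by
#' protein length in units of a million residues, so burdens of proteins of
#' very different length are comparable.
#'
#' @param n_mutations mutation count (>= 0).
#' @param n_patients cohort size (>= 1).
#' @param protein_length_aa protein length in amino acids (>= 1).
#' @return the burden, unrounded; the 2-decimal display value is in
#'   attribute `display`.
#' @examples
#' mutational_burden(26, 10182, 184)    # 13.88
#' mutational_burden(203, 10182, 1104)  # 18.06
#' @export
mutational_burden <- function(n_mutations, n_patients, protein_length_aa) {
  stop_if_not_scalar_number(n_mutations, "n_mutations", 0)
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("`n_patients` must be >= 1", call. = FALSE)
  if (!is.numeric(protein_length_aa) || protein_length_aa < 1)
    stop("`protein_length_aa` must be >= 1", call. = FALSE)
  mb <- n_mutations / (n_patients * protein_length_aa * 1e-6)
  attr(mb, "display") <- sprintf("%.2f", mb)
  mb
}

#' Per-gene burden table from a mutation table
#'
#' Counts point missense mutations per gene and normalises each count by the
#' cohort size and the gene's protein length.
#'
#' @param records mutation data frame.
#' @param n_patients cohort size.
#' @param gene_lengths named vector, gene -> protein length (aa).
#' @return data frame `gene`, `n_mutations`, `n_patients`,
#'   `protein_length_aa`, `mb`.
#' @export
cohort_burden <- function(records, n_patients, gene_lengths) {
  mis <- suppressWarnings(filter_missense(records))
  genes <- names(gene_lengths)
  data.frame(
    gene = genes,
    n_mutations = vapply(genes, function(g) sum(mis$gene == g), 0L),
    n_patients = n_patients,
    protein_length_aa = unname(gene_lengths),
    mb = vapply(genes, function(g)
      as.numeric(mutational_burden(sum(mis$gene == g), n_patients,
                                   gene_lengths[[g]])), 0),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write MAF-like mutation tables (TSV)
#'
#' Expected columns: `patient_id`, `gene`, `variant_class`,
#' `protein_change`.
#' @param file path of the TSV.
#' @param records mutation data frame.
#' @return `read_maf` returns the mutation data frame.
#' @export
read_maf <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("patient_id", "gene", "variant_class", "protein_change")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("MAF table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_maf
#' @export
write_maf <- function(records, file) {
  utils::write.table(records, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
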