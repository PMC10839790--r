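#' Somatic filter thresholds
#'
#' Defaults reproduce the tumor/normal extraction rule used for
#' antigen-presentation genes: a variant passes when the normal sample
#' shows fewer than 4 mutated reads at a variant allele fraction (VAF)
#' below 0.06, and the tumor shows more than 3 mutated reads at a VAF of
#' at least 0.15.
#'
#' @param normal_max_reads Normal alt-read count must be strictly below
#'   this (default 4).
#' @param normal_max_vaf Normal VAF must be strictly below this
#'   (default 0.06).
#' @param tumor_min_reads Tumor alt-read count must be strictly above
#'   this (default 3).
#' @param tumor_min_vaf Tumor VAF must be at least this (default 0.15,
#'   inclusive).
#' @return A list of thresholds for [variant_passes()].
#' @export
somatic_thresholds <- function(normal_max_reads = 4, normal_max_vaf = 0.06,
                               tumor_min_reads = 3, tumor_min_vaf = 0.15) {
  list(normal_max_reads = normal_max_reads, normal_max_vaf = normal_max_vaf,
       tumor_min_reads = tumor_min_reads, tumor_min_vaf = tumor_min_vaf)
}

#' Apply the tumor/normal somatic variant filter
#'
#' Evaluates each variant record against the four read-count/VAF
#' conditions of [somatic_thresholds()]; all four must hold, and the
#' record must carry the upstream quality flag. Records with missing
#' counts or VAFs fail with reason `missing-data`.
#'
#' @param records Data frame with columns `n_alt`, `n_vaf` (normal
#'   alt-read count and VAF), `t_alt`, `t_vaf` (tumor), and optionally
#'   `qual_pass` (upstream quality flag, assumed TRUE when absent).
#' @param thresholds A [somatic_thresholds()] list.
#' @return The input tibble with `pass` (logical) and `fail_reasons`
#'   (semicolon-separated failed conditions, `""` for passes) appended.
#' @examples
#' variant_passes(data.frame(n_alt = 0, n_vaf = 0, t_alt = 10, t_vaf = 0.3))
#' @export
variant_passes <- function(records, thresholds = somatic_thresholds()) {
  records <- as_tibble(records)
  if (!"qual_pass" %in% names(records)) records$qual_pass <- TRUE
  need <- c("n_alt", "n_vaf", "t_alt", "t_vaf")
  stopifnot(all(need %in% names(records)))
  missing_data <- !stats::complete.cases(records[need])
  checks <- list(
    `upstream-quality` = !isTRUE_v(records$qual_pass),
    `missing-data` = missing_data,
    `normal-reads` = !missing_data &
      !(records$n_alt < thresholds$normal_max_reads),
    `normal-vaf` = !missing_data &
      !(records$n_vaf < thresholds$normal_max_vaf),
    `tumor-reads` = !missing_data &
      !(records$t_alt > thresholds$tumor_min_reads),
    `tumor-vaf` = !missing_data &
      !(records$t_vaf >= thresholds$tumor_min_vaf)
  )
  fail_mat <- do.call(cbind, checks)
  records$pass <- rowSums(fail_mat) == 0
  records$fail_reasons <- apply(fail_mat, 1, function(r) {
    paste(names(checks)[r], collapse = ";")
  })
  records
}

isTRUE_v <- function(x) !is.na(x) & x

#' Read a named gene set
#'
#' @param path TSV with columns `gene` and optionally `set` (provenance
#'   label). The bundled default lists genes of the KEGG antigen
#'   processing and presentation pathway (hsa04612).
#' @return Character vector of unique gene symbols, with the provenance
#'   label as the `"set"` attribute.
#' @export
read_gene_set <- function(path = system.file("extdata", "app_gene_set.tsv",
                                             package = "hlacohort")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot("gene" %in% names(tab), nrow(tab) > 0)
  genes <- unique(tab$gene)
  attr(genes, "set") <- if ("set" %in% names(tab)) tab$set[1] else basename(path)
  genes
}

NON_SILENT <- c("missense", "nonsense", "frameshift", "splice-site")

#' Per-tumor somatic mutation summary over a gene set
#'
#' Restricts filter-passing variants to a gene set, drops silent variants
#' unless requested, and reports per-tumor burden and VAF order
#' statistics.
#'
#' @param records Variant records already annotated by [variant_passes()]
#'   (rows with `pass == FALSE` are ignored); must carry `sample`, `gene`,
#'   `consequence` and `t_vaf`.
#' @param genes Character vector of gene symbols ([read_gene_set()]).
#' @param include_silent Keep `silent` consequences (default FALSE;
#'   splice-site counts as non-silent).
#' @return Tibble with one row per tumor: `sample`, `n_variants`,
#'   `n_genes`, `genes` (semicolon-separated), `max_vaf`, `median_vaf`.
#' @export
summarize_somatic <- function(records, genes, include_silent = FALSE) {
  if (!"pass" %in% names(records)) records <- variant_passes(records)
  kept <- records |>
    filter(.data$pass, .data$gene %in% genes)
  if (!include_silent) {
    kept <- filter(kept, .data$consequence %in% NON_SILENT)
  }
  if (nrow(kept) == 0) {
    return(tibble(sample = character(), n_variants = integer(),
                  n_genes = integer(), genes = character(),
                  max_vaf = numeric(), median_vaf = numeric()))
  }
  kept |>
    group_by(.data$sample) |>
    summarise(
      n_variants = n(),
      n_genes = dplyr::n_distinct(.data$gene),
      genes = paste(sort(unique(.data$gene)), collapse = ";"),
      max_vaf = max(.data$t_vaf),
      median_vaf = stats::median(.data$t_vaf),
      .groups = "drop"
    )
}
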