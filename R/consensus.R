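#' Consensus typing policy
#'
#' The consensus rule runs in two stages. Stage 1 considers only the two
#' primary typing algorithms; a genotype is accepted when both determine
#' the same two alleles from two different sequencing samples. When stage 1
#' fails, stage 2 opens the supporter set to the fallback algorithms and
#' accepts a genotype determined identically by at least two algorithms
#' from two different samples.
#'
#' @param stage1 Character vector of primary algorithm names.
#' @param stage2 Character vector naming the full algorithm set used at
#'   stage 2 (defaults to stage 1 plus the common fallback typers).
#' @return A list with elements `stage1` and `stage2`.
#' @export
consensus_policy <- function(stage1 = c("HLA-HD", "HLAProfiler"),
                             stage2 = c(stage1, "Optitype", "xHLA",
                                        "HISAT-genotype")) {
  stopifnot(length(stage1) >= 1, length(stage2) >= length(stage1))
  list(stage1 = stage1, stage2 = unique(stage2))
}

# Suffix-insensitive unordered genotype key for a pair of allele names.
genotype_key <- function(a1, a2) {
  s1 <- strip_suffix(a1)
  s2 <- strip_suffix(a2)
  paste(pmin(s1, s2), pmax(s1, s2), sep = "/")
}

normalize_calls <- function(calls) {
  stopifnot(all(c("patient", "sample", "algorithm", "locus", "allele1") %in%
                  names(calls)))
  calls <- as_tibble(calls)
  if (!"allele2" %in% names(calls)) calls$allele2 <- NA_character_
  keep <- !is.na(calls$allele1)
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0) return(calls)
  calls$allele1 <- parse_allele(calls$allele1, quiet = TRUE)$allele
  # a single reported allele is stored as a putative homozygote
  calls$single_allele <- is.na(calls$allele2)
  calls$allele2 <- ifelse(calls$single_allele, calls$allele1,
                          parse_allele(ifelse(calls$single_allele,
                                              calls$allele1, calls$allele2),
                                       quiet = TRUE)$allele)
  bad <- allele_locus(calls$allele1) != calls$locus |
    allele_locus(calls$allele2) != calls$locus
  if (any(bad)) {
    stop("call alleles disagree with their locus column", call. = FALSE)
  }
  calls$genotype <- genotype_key(calls$allele1, calls$allele2)
  calls
}

empty_consensus <- function(patient, locus) {
  tibble(
    patient = patient, locus = locus, status = "no-data",
    allele1 = NA_character_, allele2 = NA_character_,
    stage = NA_integer_, n_algorithms = 0L, n_samples = 0L,
    support = "", candidates = ""
  )
}

consensus_at_stage <- function(calls, algorithms) {
  sub <- calls[calls$algorithm %in% algorithms, , drop = FALSE]
  if (nrow(sub) == 0) return(NULL)
  by_geno <- split(sub, sub$genotype)
  qual <- purrr::keep(by_geno, function(g) {
    length(unique(g$algorithm)) >= 2 && length(unique(g$sample)) >= 2
  })
  qual
}

#' Consensus genotype for one patient and locus
#'
#' Applies the two-stage agreement rule to the typing calls of a single
#' patient at a single locus. A candidate genotype (an unordered allele
#' pair, compared ignoring expression suffixes) reaches consensus when its
#' supporters span at least two distinct algorithms and two distinct
#' sequencing samples; stage 1 restricts supporters to the primary
#' algorithms and stage 2 opens the full set. When several candidates
#' qualify at the deciding stage the locus is reported unresolved with all
#' candidates listed. A call reporting a single allele supports only the
#' corresponding homozygous candidate.
#'
#' @param calls Data frame of typing calls with columns `patient`,
#'   `sample`, `algorithm`, `locus`, `allele1`, `allele2` (`NA` for a
#'   single-allele call). All rows must share one patient and one locus.
#' @param policy A [consensus_policy()].
#' @return One-row tibble: `patient`, `locus`, `status` (`consensus`,
#'   `unresolved` or `no-data`), `allele1`/`allele2` (normalized winning
#'   genotype, suffixes preserved from the supporting calls), `stage`,
#'   `n_algorithms`, `n_samples`, `support` (semicolon-separated
#'   `algorithm:sample` pairs) and `candidates` (qualifying genotypes when
#'   unresolved by ambiguity).
#' @export
consensus_genotype <- function(calls, policy = consensus_policy()) {
  if (nrow(calls) == 0) {
    return(empty_consensus(NA_character_, NA_character_))
  }
  calls <- normalize_calls(calls)
  if (nrow(calls) == 0) {
    return(empty_consensus(NA_character_, NA_character_))
  }
  if (length(unique(calls$patient)) > 1 || length(unique(calls$locus)) > 1) {
    stop("consensus_genotype() expects calls for one patient and one locus",
         call. = FALSE)
  }
  patient <- calls$patient[1]
  locus <- calls$locus[1]
  for (stage in c(1L, 2L)) {
    algorithms <- if (stage == 1L) policy$stage1 else policy$stage2
    qual <- consensus_at_stage(calls, algorithms)
    if (is.null(qual) || length(qual) == 0) next
    if (length(qual) > 1) {
      out <- empty_consensus(patient, locus)
      out$status <- "unresolved"
      out$stage <- stage
      out$candidates <- paste(sort(names(qual)), collapse = ";")
      return(out)
    }
    g <- qual[[1]]
    pair <- sort(c(g$allele1[1], g$allele2[1]))
    return(tibble(
      patient = patient, locus = locus, status = "consensus",
      allele1 = pair[1], allele2 = pair[2], stage = stage,
      n_algorithms = length(unique(g$algorithm)),
      n_samples = length(unique(g$sample)),
      support = paste(sort(unique(paste(g$algorithm, g$sample, sep = ":"))),
                      collapse = ";"),
      candidates = ""
    ))
  }
  out <- empty_consensus(patient, locus)
  out$status <- "unresolved"
  out
}

#' Per-locus consensus genotypes for a cohort
#'
#' Applies [consensus_genotype()] to every (patient, locus) group.
#'
#' @param calls Data frame of typing calls for one or more patients.
#' @param policy A [consensus_policy()].
#' @return Tibble with one row per patient-locus, as in
#'   [consensus_genotype()].
#' @seealso [consensus_completeness()] for the per-patient summary.
#' @export
patient_consensus <- function(calls, policy = consensus_policy()) {
  if (nrow(calls) == 0) {
    return(empty_consensus(character(), character())[0, ])
  }
  calls |>
    group_by(.data$patient, .data$locus) |>
    group_modify(~ consensus_genotype(bind_cols(.y[rep(1, nrow(.x)),
                                                   c("patient", "locus")],
                                                .x),
                                      policy)[-(1:2)]) |>
    ungroup()
}

#' Typing completeness per patient
#'
#' @param results Per-locus consensus tibble from [patient_consensus()].
#' @param loci Locus set over which completeness is counted (default the
#'   eight classical typing loci).
#' @return Tibble with `patient`, `n_consensus`, `n_loci` and
#'   `completeness` (fraction of loci with a consensus genotype).
#' @export
consensus_completeness <- function(results, loci = HLA_CLASSICAL_LOCI) {
  results |>
    group_by(.data$patient) |>
    summarise(
      n_consensus = sum(.data$status == "consensus" & .data$locus %in% loci),
      n_loci = length(loci),
      completeness = .data$n_consensus / .data$n_loci,
      .groups = "drop"
    )
}
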