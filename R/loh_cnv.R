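CNV_CATEGORIES <- c("biallelic-loss", "LOH", "CN-LOH", "LOH+amplification",
                    "LOH+gain", "none", "unclassifiable")

# Severity precedence when several segments overlap one gene.
CNV_PRECEDENCE <- c("biallelic-loss" = 1, "LOH" = 2, "CN-LOH" = 3,
                    "LOH+amplification" = 4, "LOH+gain" = 5, "none" = 6,
                    "unclassifiable" = 7)

#' Read allele-specific copy-number segments
#'
#' Accepts the segment-table dialect of allele-specific copy-number
#' callers: columns `sample`, `chromosome`, `start.pos`/`start`,
#' `end.pos`/`end`, `CNt` (total copy number), `A` (major-allele copies)
#' and `B` (minor-allele copies). Coordinates are 1-based inclusive.
#'
#' @param path TSV path.
#' @return Tibble with `sample`, `chromosome`, `start`, `end`, `CNt`,
#'   `A`, `B`.
#' @export
read_segments <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  nm <- names(tab)
  nm[nm == "start.pos"] <- "start"
  nm[nm == "end.pos"] <- "end"
  names(tab) <- nm
  need <- c("sample", "chromosome", "start", "end", "CNt")
  stopifnot(all(need %in% names(tab)))
  if (!"A" %in% names(tab)) tab$A <- NA_integer_
  if (!"B" %in% names(tab)) tab$B <- NA_integer_
  bad <- !is.na(tab$start) & !is.na(tab$end) & tab$end < tab$start
  if (any(bad)) {
    stop("segment end < start at line(s) ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  as_tibble(tab[c("sample", "chromosome", "start", "end", "CNt", "A", "B")])
}

#' Read sample cellularity/ploidy profiles
#'
#' @param path TSV with columns `sample`, `cellularity` (tumor-cell
#'   fraction in the specimen) and `ploidy` (mean tumor genome copy
#'   number).
#' @return Tibble.
#' @export
read_sample_profiles <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("sample", "cellularity", "ploidy") %in% names(tab)))
  if (any(tab$cellularity < 0 | tab$cellularity > 1, na.rm = TRUE)) {
    stop("cellularity outside [0, 1]", call. = FALSE)
  }
  as_tibble(tab)
}

#' Read a gene annotation table
#'
#' @param path TSV (columns `gene`, `chromosome`, `start`, `end`,
#'   optional `role`) with 1-based inclusive coordinates, or a BED file
#'   (0-based half-open, converted on read with a message). Roles tag
#'   genes for prevalence policies: `HLA-classI`, `HLA-classII`, `APP`,
#'   `B2M`, `CIITA` or `other`.
#' @param format `"tsv"` or `"bed"`.
#' @return Tibble with `gene`, `chromosome`, `start`, `end`, `role`.
#' @export
read_gene_annotation <- function(path = system.file("extdata",
                                                    "hla_region_genes.tsv",
                                                    package = "hlacohort"),
                                 format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    tab <- readr::read_tsv(path,
                           col_names = c("chromosome", "start", "end",
                                         "gene"),
                           col_types = "ciic", progress = FALSE)
    tab$start <- tab$start + 1L   # BED is 0-based half-open
    message("BED coordinates converted to 1-based inclusive")
    tab$role <- "other"
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
    if (!"role" %in% names(tab)) tab$role <- "other"
  }
  stopifnot(all(c("gene", "chromosome", "start", "end") %in% names(tab)),
            all(tab$end >= tab$start))
  as_tibble(tab[c("gene", "chromosome", "start", "end", "role")])
}

#' Read chromosome-arm definitions
#'
#' @param path TSV with columns `arm`, `chromosome`, `start`, `end`
#'   (1-based inclusive).
#' @return Tibble.
#' @export
read_arm_definitions <- function(path = system.file("extdata", "arms.tsv",
                                                    package = "hlacohort")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("arm", "chromosome", "start", "end") %in% names(tab)))
  as_tibble(tab)
}

overlap_bases <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
}

#' Filter segments by size, cellularity and gene content
#'
#' Retains segments of at least `min_size` bases, from samples with tumor
#' cellularity at least `min_cellularity`, overlapping at least one
#' annotated target gene. Every rejection is logged with its reason.
#'
#' @param segments Segment tibble ([read_segments()]) or a TSV path.
#' @param profiles Sample profile tibble ([read_sample_profiles()]);
#'   samples without a profile are rejected.
#' @param genes Gene annotation tibble ([read_gene_annotation()]).
#' @param min_size Minimal segment size in bases (default 50 kb).
#' @param min_cellularity Minimal tumor-cell fraction (default 0.2).
#' @return List with `retained` (segment tibble) and `rejected` (segment
#'   tibble with a `reason` column).
#' @export
load_segments <- function(segments, profiles, genes,
                          min_size = 50000, min_cellularity = 0.2) {
  if (is.character(segments)) segments <- read_segments(segments)
  segments <- as_tibble(segments)
  segments$size <- segments$end - segments$start + 1
  cell <- profiles$cellularity[match(segments$sample, profiles$sample)]
  has_gene <- purrr::pmap_lgl(
    segments[c("chromosome", "start", "end")],
    function(chromosome, start, end) {
      any(genes$chromosome == chromosome &
            overlap_bases(start, end, genes$start, genes$end) >= 1)
    })
  reason <- dplyr::case_when(
    is.na(cell) ~ "no-sample-profile",
    cell < min_cellularity ~ "low-cellularity",
    segments$size < min_size ~ "below-min-size",
    !has_gene ~ "no-target-gene",
    TRUE ~ NA_character_
  )
  rejected <- segments[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  if (nrow(rejected) > 0) {
    message(nrow(rejected), " segment(s) rejected: ",
            paste(sprintf("%s=%d", names(table(rejected$reason)),
                          table(rejected$reason)), collapse = ", "))
  }
  list(retained = segments[is.na(reason), , drop = FALSE],
       rejected = rejected)
}

# Amplification threshold on total copy number, given tumor ploidy.
# The rule is stated on integer ploidy; fractional ploidy is rounded
# half-up. Above ploidy 9 no amplification call is made (gain instead).
amplification_threshold <- function(ploidy) {
  rp <- floor(ploidy + 0.5)
  dplyr::case_when(
    rp <= 2 ~ 7,
    rp <= 9 ~ 1 + 2 * rp,
    TRUE ~ Inf
  )
}

#' Classify an allele-specific copy-number state into an LOH category
#'
#' Categories follow allele-specific copy-number conventions, with CNA the
#' copy number of the retained (major) allele: biallelic loss when total
#' copy number CNt is zero; LOH when the minor allele is lost and
#' CNA = CNt = 1; copy-neutral LOH (CN-LOH) when CNA = CNt = 2; LOH with
#' gain when CNA = CNt >= 3; the gain is an amplification when CNt
#' reaches 7 at ploidy 2, or 1 + 2*ploidy at ploidy 3 to 9. Segments
#' retaining the minor allele (B >= 1) are `none`.
#'
#' @param CNt,A,B Integer vectors: total, major-allele and minor-allele
#'   copy numbers.
#' @param ploidy Tumor ploidy (recycled; rounded half-up before applying
#'   the amplification rule).
#' @return Character vector of categories; `NA` A/B (with CNt > 0) gives
#'   `"unclassifiable"`.
#' @examples
#' classify_cn_state(CNt = c(1, 2, 0, 7, 4), A = c(1, 2, 0, 7, 4),
#'                   B = c(0, 0, 0, 0, 0), ploidy = c(2, 2, 2, 2, 3))
#' @export
classify_cn_state <- function(CNt, A, B, ploidy = 2) {
  n <- length(CNt)
  ploidy <- rep_len(ploidy, n)
  inconsistent <- !is.na(A) & !is.na(B) & A + B != CNt
  if (any(inconsistent)) {
    stop("A + B != CNt at record(s) ",
         paste(utils::head(which(inconsistent), 5L), collapse = ", "),
         call. = FALSE)
  }
  thr <- amplification_threshold(ploidy)
  dplyr::case_when(
    CNt == 0 ~ "biallelic-loss",
    is.na(A) | is.na(B) ~ "unclassifiable",
    B >= 1 ~ "none",
    A == 1 & CNt == 1 ~ "LOH",
    A == 2 & CNt == 2 ~ "CN-LOH",
    A >= 3 & CNt >= thr ~ "LOH+amplification",
    A >= 3 ~ "LOH+gain",
    TRUE ~ "unclassifiable"
  )
}

#' Classify every segment of a cohort
#'
#' @param segments Segment tibble (retained output of [load_segments()]).
#' @param profiles Sample profiles supplying per-sample ploidy.
#' @return The segment tibble with a `category` column appended.
#' @export
classify_segments <- function(segments, profiles) {
  ploidy <- profiles$ploidy[match(segments$sample, profiles$sample)]
  segments$category <- classify_cn_state(segments$CNt, segments$A,
                                         segments$B, ploidy)
  segments
}

#' Gene-level copy-number events
#'
#' A gene receives a segment's category when their intervals overlap by at
#' least one base. When several overlapping segments disagree, the most
#' severe category wins (biallelic loss, then LOH, CN-LOH, LOH with
#' amplification, LOH with gain, none); the full overlap table is kept as
#' the `audit` attribute.
#'
#' @param segments Classified segment tibble ([classify_segments()]).
#' @param genes Gene annotation tibble.
#' @return Tibble with one row per (sample, gene) that overlaps any
#'   segment: `sample`, `gene`, `role`, `category`, `n_segments`.
#' @export
gene_events <- function(segments, genes) {
  audit <- segments |>
    inner_join(genes, by = "chromosome", suffix = c("", ".gene"),
               relationship = "many-to-many") |>
    filter(overlap_bases(.data$start, .data$end, .data$start.gene,
                         .data$end.gene) >= 1)
  events <- audit |>
    group_by(.data$sample, .data$gene, .data$role) |>
    summarise(
      category = CNV_CATEGORIES[min(CNV_PRECEDENCE[.data$category],
                                    na.rm = TRUE)],
      n_segments = n(), .groups = "drop"
    )
  attr(events, "audit") <- audit
  events
}

#' Arm-level test for a copy-number segment
#'
#' @param segments Segment tibble.
#' @param arm One-row arm definition (`arm`, `chromosome`, `start`,
#'   `end`).
#' @param min_fraction Minimal fraction of the arm covered (default 0.9).
#' @return Logical vector: TRUE where the segment covers at least
#'   `min_fraction` of the arm length (FALSE off-chromosome).
#' @export
is_arm_level <- function(segments, arm, min_fraction = 0.9) {
  stopifnot(nrow(arm) == 1)
  arm_len <- arm$end - arm$start + 1
  ov <- overlap_bases(segments$start, segments$end, arm$start, arm$end)
  segments$chromosome == arm$chromosome & ov / arm_len >= min_fraction
}

#' LOH prevalence per gene under the category counting policies
#'
#' For HLA genes every LOH-bearing category (LOH, CN-LOH, LOH with gain or
#' amplification) counts toward prevalence, and patients who are germline
#' homozygous at the gene are removed from the denominator (reference-based
#' analysis cannot detect LOH without germline heterozygosity). For B2M
#' and CIITA only LOH and biallelic loss count. Optional gene sets report
#' tumors with qualifying events at every listed gene.
#'
#' @param events Gene-level event tibble ([gene_events()]) with a
#'   `patient` column (add one if samples map 1:1 to patients).
#' @param patients Character vector of evaluable tumors (the denominator
#'   universe).
#' @param germline Optional tibble `patient`, `gene`, `homozygous`; for
#'   HLA-role genes, homozygous (or missing) patients are excluded from
#'   that gene's denominator.
#' @param restricted_genes Genes counted under the LOH/biallelic-loss-only
#'   policy (default B2M and CIITA).
#' @param gene_sets Optional named list of gene vectors for joint
#'   prevalence.
#' @return Tibble with `measure`, `qualifying`, `n_events`,
#'   `n_denominator`, `prevalence`.
#' @export
loh_prevalence <- function(events, patients, germline = NULL,
                           restricted_genes = c("B2M", "CIITA"),
                           gene_sets = NULL) {
  hla_qual <- c("LOH", "CN-LOH", "LOH+gain", "LOH+amplification")
  restricted_qual <- c("LOH", "biallelic-loss")
  stopifnot("patient" %in% names(events))
  genes <- sort(unique(events$gene))
  qualifying_patients <- function(gene) {
    qual <- if (gene %in% restricted_genes) restricted_qual else hla_qual
    unique(events$patient[events$gene == gene & events$category %in% qual])
  }
  denominator <- function(gene) {
    denom <- patients
    if (!gene %in% restricted_genes && !is.null(germline)) {
      g <- germline[germline$gene == gene, , drop = FALSE]
      hom <- g$patient[g$homozygous]
      missing <- setdiff(patients, g$patient)
      if (length(missing) > 0) {
        message(length(missing), " patient(s) without germline genotype ",
                "at ", gene, " excluded from denominator")
      }
      denom <- setdiff(patients, c(hom, missing))
    }
    denom
  }
  per_gene <- purrr::map(genes, function(gene) {
    denom <- denominator(gene)
    hits <- intersect(qualifying_patients(gene), denom)
    tibble(measure = gene,
           qualifying = if (gene %in% restricted_genes)
             "LOH|biallelic-loss" else "any-LOH",
           n_events = length(hits), n_denominator = length(denom),
           prevalence = length(hits) / max(length(denom), 1))
  })
  per_set <- purrr::imap(gene_sets %||% list(), function(gs, nm) {
    denoms <- purrr::map(gs, denominator)
    denom <- Reduce(intersect, denoms)
    hits <- Reduce(intersect, c(purrr::map(gs, qualifying_patients),
                                list(denom)))
    tibble(measure = nm, qualifying = "all-genes",
           n_events = length(hits), n_denominator = length(denom),
           prevalence = length(hits) / max(length(denom), 1))
  })
  bind_rows(bind_rows(per_gene), bind_rows(per_set))
}
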