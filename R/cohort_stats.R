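consensus_only <- function(genotypes, quiet = FALSE) {
  if ("status" %in% names(genotypes)) {
    dropped <- sum(genotypes$status != "consensus")
    if (dropped > 0 && !quiet) {
      message(dropped, " non-consensus patient-locus record(s) excluded")
    }
    genotypes <- genotypes[genotypes$status == "consensus", , drop = FALSE]
  }
  genotypes
}

#' Cohort allele frequencies at one locus
#'
#' The frequency of an allele is its number of occurrences divided by the
#' number of chromosomes (2N); a homozygote contributes two occurrences.
#' Individuals without a consensus genotype at the locus are excluded (and
#' counted via a message), never imputed.
#'
#' @param genotypes Data frame with columns `patient`, `locus`, `allele1`,
#'   `allele2`, optionally `status` (only `"consensus"` rows are used).
#' @param locus Locus to tabulate.
#' @param ignore_suffix Strip expression suffixes before counting
#'   (default TRUE, matching the comparison convention used throughout).
#' @return Tibble with `locus`, `allele`, `count`, `frequency`,
#'   `n_chromosomes`.
#' @export
allele_frequencies <- function(genotypes, locus, ignore_suffix = TRUE) {
  g <- consensus_only(genotypes)
  g <- g[g$locus == locus, , drop = FALSE]
  if (nrow(g) == 0) {
    return(tibble(locus = character(), allele = character(),
                  count = integer(), frequency = numeric(),
                  n_chromosomes = integer()))
  }
  a <- c(g$allele1, ifelse(is.na(g$allele2), g$allele1, g$allele2))
  if (ignore_suffix) a <- strip_suffix(a)
  n_chrom <- 2L * nrow(g)
  tab <- table(a)
  tibble(
    locus = locus,
    allele = names(tab),
    count = as.integer(tab),
    frequency = as.integer(tab) / n_chrom,
    n_chromosomes = n_chrom
  ) |> arrange(desc(.data$frequency), .data$allele)
}

#' Homozygosity rates per locus and over locus sets
#'
#' An individual is homozygous at a locus when its consensus genotype has
#' two identical alleles at two-field resolution (ignoring expression
#' suffixes); a single detected allele counts as homozygous. Multi-locus
#' rates give the fraction of individuals homozygous at at least `k` loci
#' of a named set, and joint rates the fraction homozygous at every locus
#' of a set.
#'
#' @param genotypes Consensus genotype data frame (`patient`, `locus`,
#'   `allele1`, `allele2`, optional `status`).
#' @param locus_sets Optional named list of locus vectors for joint
#'   homozygosity (homozygous at every listed locus).
#' @param at_least Optional named list of `list(loci =, k =)` entries for
#'   at-least-k homozygosity rates.
#' @return Tibble with `measure` (locus symbol or set name), `kind`
#'   (`"locus"`, `"joint"` or `"at-least"`), `n_homozygous`, `n` and
#'   `rate`.
#' @export
homozygosity_rates <- function(genotypes, locus_sets = NULL,
                               at_least = NULL) {
  g <- consensus_only(genotypes, quiet = TRUE)
  g$hom <- strip_suffix(g$allele1) ==
    strip_suffix(ifelse(is.na(g$allele2), g$allele1, g$allele2))
  per_locus <- g |>
    group_by(measure = .data$locus) |>
    summarise(kind = "locus", n_homozygous = sum(.data$hom), n = n(),
              rate = mean(.data$hom), .groups = "drop")
  wide <- g |>
    select("patient", "locus", "hom") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "hom")
  joint_rows <- purrr::imap(locus_sets %||% list(), function(loci, nm) {
    stopifnot(all(loci %in% names(wide)))
    m <- as.matrix(wide[loci])
    complete <- stats::complete.cases(m)
    hits <- rowSums(m[complete, , drop = FALSE]) == length(loci)
    tibble(measure = nm, kind = "joint", n_homozygous = sum(hits),
           n = sum(complete), rate = mean(hits))
  })
  atleast_rows <- purrr::imap(at_least %||% list(), function(spec, nm) {
    stopifnot(all(spec$loci %in% names(wide)))
    m <- as.matrix(wide[spec$loci])
    complete <- stats::complete.cases(m)
    hits <- rowSums(m[complete, , drop = FALSE]) >= spec$k
    tibble(measure = nm, kind = "at-least", n_homozygous = sum(hits),
           n = sum(complete), rate = mean(hits))
  })
  bind_rows(per_locus, bind_rows(joint_rows), bind_rows(atleast_rows))
}

#' Screening criteria for allele over/under-representation
#'
#' Three criteria flag alleles whose cohort frequency departs from a
#' control population: (i) frequency at least `floor_either` in either
#' group with frequency ratio (patients/controls) at or beyond
#' `ratio_strong`; (ii) frequency at least `floor_both` in both groups
#' with ratio at or beyond `ratio_mild`; (iii) allele not detected in
#' patients while its control frequency is at least `absent_floor`.
#'
#' @param floor_either,floor_both Frequency floors for criteria i and ii.
#' @param ratio_strong,ratio_mild Length-2 numeric `c(lower, upper)` ratio
#'   bounds for criteria i and ii.
#' @param absent_floor Control-frequency floor for criterion iii.
#' @return A list of thresholds consumed by [screen_alleles()].
#' @export
screening_criteria <- function(floor_either = 0.1, floor_both = 0.1,
                               ratio_strong = c(0.5, 2),
                               ratio_mild = c(0.67, 1.5),
                               absent_floor = 0.07) {
  list(floor_either = floor_either, floor_both = floor_both,
       ratio_strong = ratio_strong, ratio_mild = ratio_mild,
       absent_floor = absent_floor)
}

#' Screen cohort allele frequencies against controls
#'
#' Evaluates every allele in the union of the two tables against the three
#' criteria of [screening_criteria()], in order i, ii, iii; the first
#' criterion that fires is recorded. Direction follows the frequency
#' ratio: at or below the lower bound is underrepresented, at or above the
#' upper bound overrepresented. An allele present in patients but absent
#' from controls has an undefined ratio and is flagged `patient-only`.
#'
#' @param patients,controls Frequency tables with columns `allele` and
#'   `frequency` on the same locus (e.g. from [allele_frequencies()];
#'   absent alleles are treated as frequency zero).
#' @param criteria A [screening_criteria()] list.
#' @return Tibble with `allele`, `freq_patients`, `freq_controls`, `ratio`
#'   (`NA` when undefined), `flag` (`underrepresented`, `overrepresented`,
#'   `not-detected`, `patient-only` or `none`) and `criterion` (`"i"`,
#'   `"ii"`, `"iii"` or `NA`).
#' @export
screen_alleles <- function(patients, controls,
                           criteria = screening_criteria()) {
  all_alleles <- sort(union(patients$allele, controls$allele))
  fp <- patients$frequency[match(all_alleles, patients$allele)]
  fc <- controls$frequency[match(all_alleles, controls$allele)]
  fp[is.na(fp)] <- 0
  fc[is.na(fc)] <- 0
  out <- tibble(allele = all_alleles, freq_patients = fp,
                freq_controls = fc,
                ratio = ifelse(fc > 0, fp / fc, NA_real_),
                flag = "none", criterion = NA_character_)
  patient_only <- fp > 0 & fc == 0
  out$flag[patient_only] <- "patient-only"
  direction <- function(r, bounds) {
    dplyr::case_when(
      r <= bounds[1] ~ "underrepresented",
      r >= bounds[2] ~ "overrepresented",
      TRUE ~ "none"
    )
  }
  undecided <- out$flag == "none" & !is.na(out$ratio)
  # criterion i
  i_fires <- undecided & (fp >= criteria$floor_either |
                            fc >= criteria$floor_either) &
    direction(out$ratio, criteria$ratio_strong) != "none"
  out$flag[i_fires] <- direction(out$ratio[i_fires], criteria$ratio_strong)
  out$criterion[i_fires] <- "i"
  # criterion ii
  undecided <- undecided & !i_fires
  ii_fires <- undecided & fp >= criteria$floor_both &
    fc >= criteria$floor_both &
    direction(out$ratio, criteria$ratio_mild) != "none"
  out$flag[ii_fires] <- direction(out$ratio[ii_fires], criteria$ratio_mild)
  out$criterion[ii_fires] <- "ii"
  # criterion iii: absent in patients, common in controls
  iii_fires <- out$flag == "none" & is.na(out$criterion) & fp == 0 &
    fc >= criteria$absent_floor
  out$flag[iii_fires] <- "not-detected"
  out$criterion[iii_fires] <- "iii"
  class(out) <- c("hla_screen", class(out))
  out
}

#' Assign superpopulation ancestry from ancestry fractions
#'
#' A patient is assigned the unique superpopulation whose ancestry
#' fraction meets the threshold (inclusive); with no fraction at the
#' threshold the patient is classified admixed.
#'
#' @param profiles Data frame with column `patient` and one fraction
#'   column per superpopulation (`EUR`, `AFR`, `AMR`, `EAS`, `SAS`).
#' @param threshold Assignment threshold on the ancestry fraction
#'   (default 0.70).
#' @return The input tibble with an `ancestry` column appended.
#' @export
assign_ancestry <- function(profiles, threshold = 0.70) {
  pops <- c("EUR", "AFR", "AMR", "EAS", "SAS")
  stopifnot(all(pops %in% names(profiles)), threshold > 0.5)
  m <- as.matrix(profiles[pops])
  if (any(m < 0 | m > 1)) stop("ancestry fractions outside [0, 1]",
                               call. = FALSE)
  if (any(rowSums(m) > 1 + 1e-6)) {
    stop("ancestry fractions sum above 1", call. = FALSE)
  }
  hits <- m >= threshold
  if (any(rowSums(hits) > 1)) {
    stop("more than one superpopulation above threshold; check input",
         call. = FALSE)
  }
  idx <- apply(hits, 1, function(r) if (any(r)) which(r)[1] else NA_integer_)
  out <- as_tibble(profiles)
  out$ancestry <- ifelse(is.na(idx), "admixed", pops[idx])
  out
}

#' Read a control allele-frequency table
#'
#' @param path TSV with columns `locus`, `allele`, `frequency` and
#'   optionally `source`. When several sources report the same allele the
#'   mean frequency across sources is taken (unweighted by default).
#' @param weights Optional named numeric vector of source weights.
#' @return Tibble with `locus`, `allele`, `frequency`.
#' @export
read_control_frequencies <- function(path, weights = NULL) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  stopifnot(all(c("locus", "allele", "frequency") %in% names(tab)))
  tab$allele <- strip_suffix(parse_allele(tab$allele, quiet = TRUE)$allele)
  if (!"source" %in% names(tab)) tab$source <- "control"
  tab$w <- if (is.null(weights)) 1 else unname(weights[tab$source])
  tab |>
    group_by(.data$locus, .data$allele) |>
    summarise(frequency = sum(.data$frequency * .data$w) / sum(.data$w),
              .groups = "drop")
}
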