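#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# Closed set of loci handled by the package: the eight classical typing loci,
# the DRB3/4/5 paralogues, and the non-classical class I genes.
HLA_LOCI <- c(
  "A", "B", "C", "DRB1", "DRB3", "DRB4", "DRB5",
  "DQA1", "DQB1", "DPA1", "DPB1", "E", "F", "G"
)

# Classical loci used for consensus completeness summaries.
HLA_CLASSICAL_LOCI <- c("A", "B", "C", "DRB1", "DQA1", "DQB1", "DPA1", "DPB1")

EXPRESSION_SUFFIXES <- c("N", "L", "S", "Q")

#' Loci recognized by the package
#'
#' @return Character vector of HLA locus symbols handled throughout the
#'   package (classical class I and II typing loci, DRB3/4/5, and the
#'   non-classical class I genes E, F and G).
#' @export
hla_loci <- function() HLA_LOCI

#' Parse HLA allele names at two-field resolution
#'
#' Parses allele names of the form `"HLA-A*02:01"`, `"A*02:01"` or
#' `"DRB4*01:03N"` into their components. Names are truncated to two fields
#' (allele group and protein number, the "4-digit" resolution of
#' sequencing-based typing); fields beyond the second are discarded with a
#' message. Expression suffixes (N, L, S, Q) are preserved.
#'
#' @param text Character vector of allele names. The optional `"HLA-"`
#'   prefix is accepted and stripped.
#' @param quiet Suppress the message emitted when higher-resolution fields
#'   are discarded.
#' @return A tibble with one row per input: `locus`, `field1`, `field2`
#'   (integers), `suffix` (`NA` when absent), `allele` (the normalized
#'   two-field rendering) and `raw` (the input text).
#' @examples
#' parse_allele(c("HLA-A*02:01", "DRB4*01:03N", "B*07:02:01"))
#' @export
parse_allele <- function(text, quiet = FALSE) {
  stopifnot(is.character(text))
  m <- regmatches(
    text,
    regexec("^(?:HLA-)?([A-Z]+[0-9]*)\\*([0-9]+):([0-9]+)((?::[0-9]+)*)([NLSQ]?)$", text)
  )
  bad <- vapply(m, length, 1L) == 0L
  if (any(bad)) {
    stop("malformed HLA allele name(s): ",
         paste(utils::head(text[bad], 5L), collapse = ", "), call. = FALSE)
  }
  parts <- do.call(rbind, m)
  locus <- parts[, 2L]
  unknown <- !locus %in% HLA_LOCI
  if (any(unknown)) {
    stop("unknown HLA locus in: ",
         paste(utils::head(text[unknown], 5L), collapse = ", "), call. = FALSE)
  }
  extra <- nzchar(parts[, 5L])
  if (any(extra) && !quiet) {
    message(sum(extra), " allele name(s) given beyond two-field resolution; ",
            "extra fields discarded")
  }
  suffix <- ifelse(nzchar(parts[, 6L]), parts[, 6L], NA_character_)
  out <- tibble(
    locus = locus,
    field1 = as.integer(parts[, 3L]),
    field2 = as.integer(parts[, 4L]),
    suffix = suffix,
    raw = text
  )
  if (any(out$field1 < 1L | out$field2 < 1L)) {
    stop("allele fields must be >= 1", call. = FALSE)
  }
  out$allele <- render_allele(out)
  out[c("locus", "field1", "field2", "suffix", "allele", "raw")]
}

#' Render parsed alleles back to normalized two-field names
#'
#' @param alleles A tibble as returned by [parse_allele()], or individual
#'   component vectors via `locus`, `field1`, `field2`, `suffix`.
#' @param locus,field1,field2,suffix Components, used when `alleles` is NULL.
#' @return Character vector of names such as `"A*02:01"` or `"DRB4*01:03N"`.
#' @export
render_allele <- function(alleles = NULL, locus = NULL, field1 = NULL,
                          field2 = NULL, suffix = NULL) {
  if (!is.null(alleles)) {
    locus <- alleles$locus; field1 <- alleles$field1
    field2 <- alleles$field2; suffix <- alleles$suffix
  }
  sfx <- ifelse(is.na(suffix), "", suffix)
  sprintf("%s*%02d:%02d%s", locus, field1, field2, sfx)
}

# Strip an expression suffix from a normalized allele string.
strip_suffix <- function(allele) {
  sub("[NLSQ]$", "", allele)
}

allele_locus <- function(allele) {
  sub("\\*.*$", "", allele)
}

#' Read a G-group equivalence table
#'
#' G groups collect alleles with identical nucleotide sequence over the
#' exons encoding the peptide-binding domains; many typing methods cannot
#' distinguish alleles within a group. The table is a TSV with columns
#' `locus`, `allele` (two-field name) and `g_group`. Alleles absent from
#' the table form their own singleton group.
#'
#' @param path Path to the TSV file. The default reads the small table
#'   bundled with the package.
#' @return A tibble with columns `locus`, `allele` (normalized) and
#'   `g_group`.
#' @export
read_g_group_table <- function(path = system.file("extdata", "g_groups.tsv",
                                                  package = "hlacohort")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  stopifnot(all(c("locus", "allele", "g_group") %in% names(tab)))
  tab$allele <- parse_allele(tab$allele, quiet = TRUE)$allele
  if (anyDuplicated(tab$allele)) {
    stop("G-group table assigns an allele to more than one group", call. = FALSE)
  }
  as_tibble(tab[c("locus", "allele", "g_group")])
}

#' G-group identifier of alleles
#'
#' @param allele Character vector of normalized allele names.
#' @param g_table G-group table from [read_g_group_table()], or NULL.
#' @return Character vector of group identifiers; an allele not listed in
#'   the table (or with `g_table = NULL`) is its own singleton group, named
#'   by its suffix-stripped two-field name.
#' @export
g_group_of <- function(allele, g_table = NULL) {
  base <- strip_suffix(allele)
  if (is.null(g_table)) return(base)
  idx <- match(base, g_table$allele)
  ifelse(is.na(idx), base, g_table$g_group[idx])
}

#' Compare two alleles for equivalence
#'
#' @param a,b Character vectors of allele names (parsed internally; must be
#'   on the same locus position-wise).
#' @param mode `"exact"` compares (field1, field2, suffix); `"ignore-suffix"`
#'   drops the expression suffix (null alleles such as DRB4*01:03N are not
#'   distinguishable from DRB4*01:03 by sequencing-based typing);
#'   `"g-group"` is true when both alleles map to the same G group.
#' @param g_table G-group table, required only for `mode = "g-group"`.
#' @return Logical vector.
#' @examples
#' alleles_equivalent("DRB4*01:03", "DRB4*01:03N", mode = "ignore-suffix")
#' @export
alleles_equivalent <- function(a, b,
                               mode = c("exact", "ignore-suffix", "g-group"),
                               g_table = NULL) {
  mode <- match.arg(mode)
  pa <- parse_allele(a, quiet = TRUE)
  pb <- parse_allele(b, quiet = TRUE)
  if (any(pa$locus != pb$locus)) {
    stop("alleles_equivalent() compares alleles on the same locus; got ",
         paste(utils::head(paste(pa$locus, "vs", pb$locus)[pa$locus != pb$locus], 3L),
               collapse = ", "), call. = FALSE)
  }
  switch(mode,
    "exact" = pa$allele == pb$allele,
    "ignore-suffix" = strip_suffix(pa$allele) == strip_suffix(pb$allele),
    "g-group" = g_group_of(pa$allele, g_table) == g_group_of(pb$allele, g_table)
  )
}
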