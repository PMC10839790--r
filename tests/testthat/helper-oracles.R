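# Independent brute-force oracles used across tests. These deliberately
# re-derive results by exhaustive enumeration or direct transcription of
# the filtering rules, without calling the implementation under test.

# All unordered haplotype pairs compatible with a genotype, by exhaustive
# enumeration of every per-locus phase assignment.
brute_diplotypes <- function(genotype, loci = genotype$locus) {
  g <- genotype[match(loci, genotype$locus), , drop = FALSE]
  a1 <- g$allele1
  a2 <- ifelse(is.na(g$allele2), g$allele1, g$allele2)
  L <- length(loci)
  combos <- expand.grid(rep(list(c(1, 2)), L))
  pairs <- apply(combos, 1, function(ch) {
    h1 <- ifelse(ch == 1, a1, a2)
    h2 <- ifelse(ch == 1, a2, a1)
    s1 <- paste(h1, collapse = "~")
    s2 <- paste(h2, collapse = "~")
    paste(min(s1, s2), max(s1, s2), sep = "||")
  })
  unique(pairs)
}

# Random multilocus genotype over small per-locus allele universes.
random_genotype <- function(loci = c("A", "B", "C"), n_alleles = 4) {
  alleles <- lapply(loci, function(l)
    sprintf("%s*%02d:01", l, seq_len(n_alleles)))
  tibble::tibble(
    locus = loci,
    allele1 = vapply(alleles, function(u) sample(u, 1), ""),
    allele2 = vapply(alleles, function(u) sample(u, 1), "")
  )
}

# Direct transcription of the copy-number classification rules.
brute_cn_category <- function(CNt, A, B, ploidy) {
  if (CNt == 0) return("biallelic-loss")
  if (is.na(A) || is.na(B)) return("unclassifiable")
  if (B >= 1) return("none")
  if (A == 1 && CNt == 1) return("LOH")
  if (A == 2 && CNt == 2) return("CN-LOH")
  if (A >= 3 && A == CNt) {
    rp <- floor(ploidy + 0.5)
    amp <- if (rp <= 2) CNt >= 7
           else if (rp <= 9) CNt >= 1 + 2 * rp
           else FALSE
    return(if (amp) "LOH+amplification" else "LOH+gain")
  }
  "unclassifiable"
}

# Direct transcription of the somatic read-count/VAF filter.
brute_variant_pass <- function(n_alt, n_vaf, t_alt, t_vaf) {
  n_alt < 4 && n_vaf < 0.06 && t_alt > 3 && t_vaf >= 0.15
}
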