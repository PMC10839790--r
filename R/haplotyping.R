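HAP_SEP <- "~"

#' Build haplotype strings from per-locus alleles
#'
#' A multilocus haplotype is stored as the alleles of an ordered locus set
#' joined with `"~"`, e.g. `"A*01:01~B*08:01~C*07:01"`.
#'
#' @param ... Character vectors of allele names, one per locus, in
#'   canonical locus order.
#' @return Character vector of haplotype strings.
#' @export
haplotype_string <- function(...) {
  do.call(paste, c(list(...), sep = HAP_SEP))
}

split_haplotype <- function(h) {
  strsplit(h, HAP_SEP, fixed = TRUE)
}

#' Read a reference haplotype-frequency table
#'
#' The TSV carries one reference haplotype per row: a `rank` (haplotype
#' number used for variant labeling), one allele column per locus (named by
#' the locus symbol), and a `frequency` column giving the fraction of
#' chromosomes carrying the haplotype in the reference population.
#' Reference tables are usually truncated; the total frequency mass covered
#' is reported via a message.
#'
#' @param path TSV path.
#' @param loci Character vector naming the locus columns in canonical
#'   order; defaults to every recognized locus symbol found in the header.
#' @param quiet Suppress the coverage message.
#' @return A tibble with columns `label`, `haplotype`, `frequency`, with
#'   attribute `loci`.
#' @export
read_haplotype_frequencies <- function(path, loci = NULL, quiet = FALSE) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (is.null(loci)) loci <- intersect(names(tab), HLA_LOCI)
  stopifnot(length(loci) >= 1, all(loci %in% names(tab)),
            "frequency" %in% names(tab))
  alleles <- lapply(loci, function(l) parse_allele(tab[[l]], quiet = TRUE)$allele)
  out <- tibble(
    label = if ("rank" %in% names(tab)) as.character(tab$rank)
            else as.character(seq_len(nrow(tab))),
    haplotype = do.call(haplotype_string, alleles),
    frequency = as.numeric(tab$frequency)
  )
  if (any(out$frequency < 0)) stop("negative reference frequency", call. = FALSE)
  mass <- sum(out$frequency)
  if (mass > 1 + 1e-6) stop("reference frequencies sum above 1", call. = FALSE)
  if (!quiet) {
    message(sprintf("reference table covers %.1f%% of chromosome mass",
                    100 * mass))
  }
  attr(out, "loci") <- loci
  out
}

#' Enumerate the diplotypes compatible with a multilocus genotype
#'
#' For H heterozygous loci there are 2^(H-1) distinct unordered haplotype
#' pairs reproducing the genotype (one when fully homozygous).
#'
#' @param genotype Data frame with columns `locus`, `allele1`, `allele2`
#'   for one individual (`allele2` equal to `allele1`, or `NA`, at
#'   homozygous loci).
#' @param loci Canonical locus order; defaults to the order of appearance.
#' @return Tibble with columns `hap1`, `hap2` (`hap1 <= hap2`
#'   lexicographically) and uniform `weight`.
#' @export
enumerate_diplotypes <- function(genotype, loci = NULL) {
  if (nrow(genotype) == 0) stop("empty genotype", call. = FALSE)
  if (is.null(loci)) loci <- genotype$locus
  stopifnot(setequal(loci, genotype$locus), !anyDuplicated(genotype$locus))
  genotype <- genotype[match(loci, genotype$locus), , drop = FALSE]
  a1 <- genotype$allele1
  a2 <- ifelse(is.na(genotype$allele2), genotype$allele1, genotype$allele2)
  het <- which(strip_suffix(a1) != strip_suffix(a2))
  H <- length(het)
  n_free <- max(H - 1L, 0L)
  # fix the phase of the first heterozygous locus; vary the rest
  grid <- if (n_free == 0) matrix(FALSE, nrow = 1, ncol = 0) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n_free)))
  build <- function(flips) {
    h1 <- a1; h2 <- a2
    if (H > 1) {
      flip_loci <- het[-1][flips]
      h1[flip_loci] <- a2[flip_loci]
      h2[flip_loci] <- a1[flip_loci]
    }
    s1 <- paste(h1, collapse = HAP_SEP)
    s2 <- paste(h2, collapse = HAP_SEP)
    c(min(s1, s2), max(s1, s2))
  }
  pairs <- t(apply(grid, 1, build))
  out <- tibble(hap1 = pairs[, 1], hap2 = pairs[, 2]) |> distinct()
  out$weight <- 1 / nrow(out)
  out
}

# Build the per-individual compatible-pair table for a cohort:
# one row per (individual, hap1, hap2), plus the haplotype universe.
cohort_pair_table <- function(genotypes, loci) {
  split_g <- split(genotypes, genotypes$patient)
  pair_list <- purrr::imap(split_g, function(g, id) {
    d <- enumerate_diplotypes(g, loci)
    d$patient <- id
    d
  })
  pairs <- bind_rows(pair_list)
  universe <- sort(unique(c(pairs$hap1, pairs$hap2)))
  pairs$i1 <- match(pairs$hap1, universe)
  pairs$i2 <- match(pairs$hap2, universe)
  pairs$mult <- ifelse(pairs$i1 == pairs$i2, 1, 2)
  pairs$ind <- match(pairs$patient, names(split_g))
  list(pairs = pairs, universe = universe, n_ind = length(split_g))
}

#' Estimate haplotype frequencies by expectation-maximization
#'
#' Gene-counting EM over phase-ambiguous multilocus genotypes. The E-step
#' weights each compatible haplotype pair (h1, h2) of an individual by
#' f(h1) f(h2), doubled when h1 != h2, normalized per individual; the
#' M-step sets f(h) to the expected number of h chromosomes over 2N.
#' Initialization is uniform over the haplotypes compatible with at least
#' one individual, so the fit is deterministic. The log-likelihood is
#' checked to be non-decreasing at every iteration.
#'
#' @param genotypes Long data frame with columns `patient`, `locus`,
#'   `allele1`, `allele2` covering a shared locus set.
#' @param loci Canonical locus order (default: order of appearance for the
#'   first individual).
#' @param tol Convergence threshold on the maximum absolute frequency
#'   change per iteration.
#' @param max_iter Iteration cap; hitting it flags the fit non-converged.
#' @param prune Frequencies below this are dropped and the rest
#'   renormalized after convergence.
#' @return An object of class `hla_em`: frequencies (tibble `haplotype`,
#'   `frequency`, summing to one), `loglik`, `loglik_trace`, `iterations`,
#'   `converged`, `n` individuals and the locus set. Use [tidy.hla_em()]
#'   and [glance.hla_em()] to extract results.
#' @export
em_frequencies <- function(genotypes, loci = NULL, tol = 1e-8,
                           max_iter = 10000, prune = 1e-12) {
  stopifnot(nrow(genotypes) >= 1)
  if (is.null(loci)) {
    first <- genotypes$patient == genotypes$patient[1]
    loci <- genotypes$locus[first]
  }
  ct <- cohort_pair_table(genotypes, loci)
  pairs <- ct$pairs
  K <- length(ct$universe)
  N <- ct$n_ind
  f <- rep(1 / K, K)
  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  i1 <- pairs$i1; i2 <- pairs$i2; mult <- pairs$mult; ind <- pairs$ind
  repeat {
    iter <- iter + 1L
    w <- f[i1] * f[i2] * mult
    denom <- rowsum(w, ind)[, 1]
    ll <- sum(log(denom))
    if (length(ll_trace) > 0 && ll < ll_trace[length(ll_trace)] - 1e-9) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    ll_trace <- c(ll_trace, ll)
    wn <- w / denom[ind]
    counts <- rowsum(c(wn, wn), c(i1, i2))
    f_new <- numeric(K)
    f_new[as.integer(rownames(counts))] <- counts[, 1]
    f_new <- f_new / (2 * N)
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  keep <- f >= prune
  f <- f[keep] / sum(f[keep])
  out <- list(
    frequencies = tibble(haplotype = ct$universe[keep], frequency = f) |>
      arrange(desc(.data$frequency)),
    loglik = ll_trace[length(ll_trace)],
    loglik_trace = ll_trace,
    iterations = iter,
    converged = converged,
    n = N,
    loci = loci
  )
  class(out) <- "hla_em"
  out
}

#' @export
print.hla_em <- function(x, ...) {
  cat(sprintf(
    "Haplotype-frequency EM fit: %d haplotypes, %d individuals, %d iterations (%s)\n",
    nrow(x$frequencies), x$n, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("log-likelihood %.4f\n", x$loglik))
  print(utils::head(x$frequencies, 10))
  invisible(x)
}

#' Tidy a haplotype-frequency EM fit
#'
#' @param x An `hla_em` object.
#' @param ... Unused.
#' @return Tibble with `haplotype` and `frequency`.
#' @export
tidy.hla_em <- function(x, ...) x$frequencies

#' One-row summary of a haplotype-frequency EM fit
#'
#' @param x An `hla_em` object.
#' @param ... Unused.
#' @return Tibble with `n`, `n_haplotypes`, `loglik`, `iterations`,
#'   `converged`.
#' @export
glance.hla_em <- function(x, ...) {
  tibble(n = x$n, n_haplotypes = nrow(x$frequencies), loglik = x$loglik,
         iterations = x$iterations, converged = x$converged)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

ref_frequency_lookup <- function(ref, haplotypes, epsilon) {
  idx <- match(haplotypes, ref$haplotype)
  ifelse(is.na(idx), epsilon, pmax(ref$frequency[idx], epsilon))
}

#' Most likely diplotype of a genotype against a reference table
#'
#' Scores every compatible haplotype pair by f(h1) f(h2) (doubled for
#' heterozygous pairs) using reference frequencies; haplotypes absent from
#' the reference receive a small pseudo-frequency so that every pair is
#' scoreable and listed haplotypes always dominate.
#'
#' @param genotype Data frame with `locus`, `allele1`, `allele2` for one
#'   individual.
#' @param ref Reference table with columns `haplotype`, `frequency`
#'   (e.g. from [read_haplotype_frequencies()] or [tidy.hla_em()]).
#' @param epsilon Pseudo-frequency for unlisted haplotypes.
#' @param loci Canonical locus order.
#' @return Tibble ranking all compatible pairs: `hap1`, `hap2`, `score`,
#'   `prob` (scores normalized over pairs), `rank` and `ambiguous` (TRUE
#'   when the top score is tied; ties are broken lexicographically for
#'   determinism). Row 1 is the assignment.
#' @export
most_likely_diplotype <- function(genotype, ref, epsilon = 1e-9, loci = NULL) {
  d <- enumerate_diplotypes(genotype, loci)
  f1 <- ref_frequency_lookup(ref, d$hap1, epsilon)
  f2 <- ref_frequency_lookup(ref, d$hap2, epsilon)
  d$score <- f1 * f2 * ifelse(d$hap1 == d$hap2, 1, 2)
  d <- d |> arrange(desc(.data$score), .data$hap1, .data$hap2)
  d$prob <- d$score / sum(d$score)
  d$rank <- seq_len(nrow(d))
  d$ambiguous <- nrow(d) > 1 && isTRUE(all.equal(d$score[1], d$score[2]))
  d[c("hap1", "hap2", "score", "prob", "rank", "ambiguous")]
}

# Per-locus divergence between a haplotype and each reference haplotype,
# at suffix-stripped two-field resolution.
hap_divergence <- function(h, ref_haps) {
  ha <- strip_suffix(split_haplotype(h)[[1]])
  vapply(ref_haps, function(r) {
    ra <- strip_suffix(split_haplotype(r)[[1]])
    sum(ha != ra)
  }, 1L)
}

#' Classify haplotypes as known, variant or unknown
#'
#' A haplotype identical to a reference entry at two-field resolution is
#' `known`. One diverging from its closest reference at exactly one locus
#' is a `variant`, labeled with that reference's haplotype number plus a
#' suffix letter (b, c, d, ...) in discovery order; divergence only by
#' G-group membership still classifies as variant, with `g_group_flag`
#' set. A haplotype at least two loci away from every reference is
#' `unknown`. When several references sit at divergence one, the most
#' frequent is taken as the match.
#'
#' @param haplotypes Character vector of haplotype strings.
#' @param ref Reference table with `label`, `haplotype`, `frequency`.
#' @param g_table Optional G-group table used to flag G-group-only
#'   divergence.
#' @return Tibble with one row per input haplotype: `haplotype`, `class`,
#'   `matched` (reference label), `variant_label` (label + suffix for
#'   variants), `divergent_locus` and `g_group_flag`.
#' @export
classify_haplotypes <- function(haplotypes, ref, g_table = NULL) {
  if (nrow(ref) == 0) {
    warning("empty reference table: all haplotypes unknown")
    return(tibble(haplotype = haplotypes, class = "unknown",
                  matched = NA_character_, variant_label = NA_character_,
                  divergent_locus = NA_character_, g_group_flag = FALSE))
  }
  loci <- attr(ref, "loci")
  suffix_used <- list()   # per reference label: variant haplotype -> suffix
  rows <- purrr::map(haplotypes, function(h) {
    div <- hap_divergence(h, ref$haplotype)
    dmin <- min(div)
    if (dmin == 0) {
      lab <- ref$label[which(div == 0)[1]]
      return(tibble(haplotype = h, class = "known", matched = lab,
                    variant_label = NA_character_,
                    divergent_locus = NA_character_, g_group_flag = FALSE))
    }
    if (dmin == 1) {
      cand <- which(div == 1)
      best <- cand[which.max(ref$frequency[cand])]
      lab <- ref$label[best]
      ha <- strip_suffix(split_haplotype(h)[[1]])
      ra <- strip_suffix(split_haplotype(ref$haplotype[best])[[1]])
      k <- which(ha != ra)
      locus_name <- if (!is.null(loci)) loci[k] else allele_locus(ha[k])
      gflag <- !is.null(g_table) &&
        g_group_of(ha[k], g_table) == g_group_of(ra[k], g_table)
      reg <- suffix_used[[lab]] %||% character(0)
      if (h %in% names(reg)) {
        sfx <- reg[[h]]
      } else {
        sfx <- letters[length(reg) + 2L]   # first variant gets "b"
        reg[[h]] <- sfx
        suffix_used[[lab]] <<- reg
      }
      return(tibble(haplotype = h, class = "variant", matched = lab,
                    variant_label = paste0(lab, sfx),
                    divergent_locus = locus_name, g_group_flag = gflag))
    }
    tibble(haplotype = h, class = "unknown", matched = NA_character_,
           variant_label = NA_character_, divergent_locus = NA_character_,
           g_group_flag = FALSE)
  })
  bind_rows(rows)
}

#' Read the DRB1 to DRB3/4/5 linkage table
#'
#' Maps the DRB1 allele group (first field) to its serological haplotype
#' group, which determines whether the haplotype carries a DRB3, DRB4 or
#' DRB5 paralogue: DR1 and DR8 carry none, DR51 carries DRB5, DR52 carries
#' DRB3 and DR53 carries DRB4.
#'
#' @param path TSV with columns `drb1_group` (integer field1) and `group`
#'   (DR1, DR8, DR51, DR52 or DR53). Defaults to the bundled table.
#' @return Tibble `drb1_group`, `group`, `paralogue` (`""` for none).
#' @export
read_drb345_linkage <- function(path = system.file("extdata",
                                                   "drb345_linkage.tsv",
                                                   package = "hlacohort")) {
  tab <- readr::read_tsv(path, col_types = readr::cols(drb1_group = "i",
                                                       group = "c"),
                         progress = FALSE)
  paralogue <- c(DR1 = "", DR8 = "", DR51 = "DRB5", DR52 = "DRB3",
                 DR53 = "DRB4")
  stopifnot(all(tab$group %in% names(paralogue)))
  tab$paralogue <- unname(paralogue[tab$group])
  as_tibble(tab)
}

#' Resolve DRB1-DRB3/4/5 haplotype combinations
#'
#' @param allele1,allele2 Character vectors of the two DRB1 alleles per
#'   individual.
#' @param linkage Linkage table from [read_drb345_linkage()].
#' @return Tibble with `allele1`, `allele2`, `combination` (e.g.
#'   `"DRB1-DRB3/DRB1-DRB4"`, canonically ordered) and `resolved` (FALSE
#'   when a DRB1 allele group has no linkage entry).
#' @export
resolve_drb345 <- function(allele1, allele2,
                           linkage = read_drb345_linkage()) {
  hap_of <- function(a) {
    g1 <- parse_allele(a, quiet = TRUE)$field1
    idx <- match(g1, linkage$drb1_group)
    par <- linkage$paralogue[idx]
    ifelse(is.na(idx), NA_character_,
           ifelse(par == "", "DRB1", paste0("DRB1-", par)))
  }
  h1 <- hap_of(allele1)
  h2 <- hap_of(allele2)
  resolved <- !is.na(h1) & !is.na(h2)
  combo <- ifelse(resolved, paste(pmin(h1, h2), pmax(h1, h2), sep = "/"),
                  NA_character_)
  tibble(allele1 = allele1, allele2 = allele2, combination = combo,
         resolved = resolved)
}
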