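cons_row <- function(patient, locus, a1, a2) {
  tibble::tibble(patient = patient, locus = locus, status = "consensus",
                 allele1 = a1, allele2 = a2)
}

test_that("allele frequencies count occurrences over chromosomes", {
  g <- dplyr::bind_rows(
    cons_row("P1", "A", "A*01:01", "A*02:01"),
    cons_row("P2", "A", "A*01:01", "A*01:01"))
  f <- allele_frequencies(g, "A")
  expect_equal(f$frequency[f$allele == "A*01:01"], 0.75)
  expect_equal(f$frequency[f$allele == "A*02:01"], 0.25)
  expect_equal(unique(f$n_chromosomes), 4L)
  # identical homozygotes give a single allele at 1.0
  hom <- dplyr::bind_rows(cons_row("P1", "B", "B*07:02", "B*07:02"),
                          cons_row("P2", "B", "B*07:02", "B*07:02"))
  fb <- allele_frequencies(hom, "B")
  expect_equal(fb$allele, "B*07:02")
  expect_equal(fb$frequency, 1)
})

test_that("frequencies and homozygosity match a brute-force tally on random cohorts", {
  set.seed(51)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    alleles <- sprintf("A*%02d:01", 1:5)
    g <- cons_row(paste0("P", 1:n), "A",
                  sample(alleles, n, replace = TRUE),
                  sample(alleles, n, replace = TRUE))
    f <- allele_frequencies(g, "A")
    tally <- table(c(g$allele1, g$allele2)) / (2 * n)
    expect_equal(f$frequency[match(names(tally), f$allele)],
                 unname(as.numeric(tally)))
    h <- homozygosity_rates(g)
    expect_equal(h$rate, mean(g$allele1 == g$allele2))
  }
})

test_that("unresolved genotypes are excluded, not imputed", {
  g <- dplyr::bind_rows(
    cons_row("P1", "A", "A*01:01", "A*02:01"),
    tibble::tibble(patient = "P2", locus = "A", status = "unresolved",
                   allele1 = NA_character_, allele2 = NA_character_))
  expect_message(f <- allele_frequencies(g, "A"), "excluded")
  expect_equal(unique(f$n_chromosomes), 2L)
})

test_that("single detected allele counts as homozygous; suffixes ignored", {
  g <- dplyr::bind_rows(
    cons_row("P1", "DRB4", "DRB4*01:03", NA),
    cons_row("P2", "DRB4", "DRB4*01:03", "DRB4*01:03N"))
  h <- homozygosity_rates(g)
  expect_equal(h$rate, 1)
})

test_that("joint and at-least-k homozygosity follow the locus sets", {
  g <- dplyr::bind_rows(
    cons_row("P1", "A", "A*01:01", "A*01:01"),
    cons_row("P1", "B", "B*07:02", "B*07:02"),
    cons_row("P1", "C", "C*07:01", "C*07:02"),
    cons_row("P2", "A", "A*01:01", "A*02:01"),
    cons_row("P2", "B", "B*07:02", "B*07:02"),
    cons_row("P2", "C", "C*07:01", "C*07:01"))
  h <- homozygosity_rates(
    g,
    locus_sets = list(`A-B` = c("A", "B")),
    at_least = list(`classI-2plus` = list(loci = c("A", "B", "C"), k = 2)))
  expect_equal(h$rate[h$measure == "A-B"], 0.5)       # only P1
  expect_equal(h$rate[h$measure == "classI-2plus"], 1) # both have >= 2
})

test_that("fully heterozygous cohort has zero homozygosity", {
  g <- cons_row(paste0("P", 1:10), "A",
                sprintf("A*%02d:01", 1:10), sprintf("A*%02d:02", 1:10))
  expect_equal(homozygosity_rates(g)$rate, 0)
})

test_that("homozygosity under random mating tracks the sum of squared frequencies", {
  cfg <- sim_config(n_individuals = 400, pool_size = 6, miscall = 0,
                    dropout = 0, rna_silencing = 0, concentration = 2)
  sim <- simulate_cohort(cfg, seed = 13)
  # per-locus pool allele frequencies
  hap_alleles <- do.call(rbind, strsplit(sim$pool$haplotype, "~", fixed = TRUE))
  res <- patient_consensus(sim$calls)
  for (j in seq_along(cfg$loci)) {
    f <- tapply(sim$pool$frequency, hap_alleles[, j], sum)
    expected <- sum(f^2)
    se <- sqrt(expected * (1 - expected) / cfg$n_individuals)
    obs <- homozygosity_rates(res[res$locus == cfg$loci[j], ])$rate
    expect_lt(abs(obs - expected), 3 * se + 1e-12)
  }
})

test_that("the three screening criteria fire as specified", {
  pat <- tibble::tibble(allele = c("DQB1*06:02", "DQB1*03:01", "DQB1*05:01",
                                   "DQB1*02:01"),
                        frequency = c(0.066, 0.09, 0, 0.3))
  ctl <- tibble::tibble(allele = c("DQB1*06:02", "DQB1*03:01", "DQB1*05:01",
                                   "DQB1*02:01"),
                        frequency = c(0.132, 0.09, 0.07, 0.1))
  s <- screen_alleles(pat, ctl)
  r602 <- s[s$allele == "DQB1*06:02", ]
  expect_equal(r602$ratio, 0.5)
  expect_equal(r602$flag, "underrepresented")
  expect_equal(r602$criterion, "i")
  # both at 0.09: no frequency floor met, no flag
  expect_equal(s$flag[s$allele == "DQB1*03:01"], "none")
  # absent in patients with control at the 0.07 floor: criterion iii
  r501 <- s[s$allele == "DQB1*05:01", ]
  expect_equal(r501$flag, "not-detected")
  expect_equal(r501$criterion, "iii")
  # ratio 3 with both common: criterion i overrepresentation
  expect_equal(s$flag[s$allele == "DQB1*02:01"], "overrepresented")
})

test_that("criterion iii fires exactly at its control-frequency floor", {
  pat <- tibble::tibble(allele = "A*01:01", frequency = 0)
  at <- screen_alleles(pat, tibble::tibble(allele = "A*01:01",
                                           frequency = 0.07))
  below <- screen_alleles(pat, tibble::tibble(allele = "A*01:01",
                                              frequency = 0.0699))
  expect_equal(at$flag, "not-detected")
  expect_equal(below$flag, "none")
})

test_that("criterion ii catches milder ratios when both groups are common", {
  pat <- tibble::tibble(allele = "B*07:02", frequency = 0.12)
  ctl <- tibble::tibble(allele = "B*07:02", frequency = 0.19)
  s <- screen_alleles(pat, ctl)
  expect_equal(s$criterion, "ii")
  expect_equal(s$flag, "underrepresented")
})

test_that("screening is symmetric under group swap with inverted bounds", {
  set.seed(61)
  alleles <- sprintf("A*%02d:01", 1:12)
  pat <- tibble::tibble(allele = alleles, frequency = round(runif(12, 0, .3), 3))
  ctl <- tibble::tibble(allele = alleles, frequency = round(runif(12, 0.01, .3), 3))
  fwd <- screen_alleles(pat, ctl)
  swapped <- screen_alleles(ctl, pat)
  both <- dplyr::inner_join(fwd, swapped, by = "allele",
                            suffix = c(".f", ".s"))
  both <- both[both$flag.f %in% c("underrepresented", "overrepresented") &
                 both$flag.s %in% c("underrepresented", "overrepresented"), ]
  expect_true(all(
    (both$flag.f == "underrepresented") == (both$flag.s == "overrepresented")))
})

test_that("patient-only alleles report no ratio", {
  s <- screen_alleles(tibble::tibble(allele = "A*01:01", frequency = 0.05),
                      tibble::tibble(allele = character(),
                                     frequency = numeric()))
  expect_true(is.na(s$ratio))
  expect_equal(s$flag, "patient-only")
})

test_that("ancestry assignment uses an inclusive threshold", {
  prof <- tibble::tibble(patient = c("P1", "P2", "P3"),
                         EUR = c(0.85, 0.70, 0.65),
                         AFR = c(0.05, 0.10, 0.20),
                         AMR = c(0.05, 0.10, 0.10),
                         EAS = c(0.03, 0.05, 0.03),
                         SAS = c(0.02, 0.05, 0.02))
  a <- assign_ancestry(prof)
  expect_equal(a$ancestry, c("EUR", "EUR", "admixed"))
  bad <- prof
  bad$EUR[1] <- 1.5
  expect_error(assign_ancestry(bad), "outside")
})

test_that("control frequency reader averages sources", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    locus = "A", allele = c("A*01:01", "A*01:01"),
    frequency = c(0.10, 0.20), source = c("ref1", "ref2")), path)
  ctl <- read_control_frequencies(path)
  expect_equal(ctl$frequency, 0.15)
  weighted <- read_control_frequencies(path, weights = c(ref1 = 3, ref2 = 1))
  expect_equal(weighted$frequency, 0.125)
})
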