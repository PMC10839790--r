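abc_ref <- function() {
  read_haplotype_frequencies(
    system.file("extdata", "reference_haplotypes_abc_synthetic.tsv",
                package = "hlacohort"), quiet = TRUE)
}

test_that("diplotype enumeration gives 2^(H-1) unordered pairs", {
  het3 <- tibble::tibble(locus = c("A", "B", "C"),
                         allele1 = c("A*01:01", "B*07:02", "C*07:01"),
                         allele2 = c("A*02:01", "B*08:01", "C*07:02"))
  expect_equal(nrow(enumerate_diplotypes(het3)), 4L)
  hom <- tibble::tibble(locus = c("A", "B"),
                        allele1 = c("A*01:01", "B*07:02"),
                        allele2 = c("A*01:01", "B*07:02"))
  d <- enumerate_diplotypes(hom)
  expect_equal(nrow(d), 1L)
  expect_identical(d$hap1, d$hap2)
  expect_error(enumerate_diplotypes(het3[0, ]), "empty genotype")
})

test_that("enumeration matches exhaustive phase-assignment oracle", {
  set.seed(31)
  for (i in 1:60) {
    g <- random_genotype(loci = c("A", "B", "C"), n_alleles = 3)
    d <- enumerate_diplotypes(g)
    oracle <- brute_diplotypes(g)
    got <- paste(d$hap1, d$hap2, sep = "||")
    expect_setequal(got, oracle)
    H <- sum(g$allele1 != g$allele2)
    expect_equal(nrow(d), max(2^(H - 1), 1))
  }
})

test_that("EM recovers trivial cohorts exactly", {
  # all individuals homozygous for the same haplotype
  hom <- tibble::tibble(patient = rep(paste0("P", 1:5), each = 2),
                        locus = rep(c("A", "B"), 5),
                        allele1 = rep(c("A*01:01", "B*07:02"), 5),
                        allele2 = rep(c("A*01:01", "B*07:02"), 5))
  fit <- em_frequencies(hom)
  expect_equal(nrow(fit$frequencies), 1L)
  expect_equal(fit$frequencies$frequency, 1)
  expect_true(fit$converged)
})

test_that("EM equals direct phase counting when phases are determined", {
  # two-locus cohort with no double heterozygote: every phase is known
  g <- dplyr::bind_rows(
    tibble::tibble(patient = "P1", locus = c("A", "B"),
                   allele1 = c("A*01:01", "B*07:02"),
                   allele2 = c("A*02:01", "B*07:02")),
    tibble::tibble(patient = "P2", locus = c("A", "B"),
                   allele1 = c("A*01:01", "B*07:02"),
                   allele2 = c("A*01:01", "B*08:01")),
    tibble::tibble(patient = "P3", locus = c("A", "B"),
                   allele1 = c("A*01:01", "B*07:02"),
                   allele2 = c("A*01:01", "B*07:02"))
  )
  fit <- em_frequencies(g)
  counts <- c("A*01:01~B*07:02" = 4, "A*02:01~B*07:02" = 1,
              "A*01:01~B*08:01" = 1)  # direct chromosome tally
  expect_equal(
    fit$frequencies$frequency[match(names(counts), fit$frequencies$haplotype)],
    unname(counts) / 6, tolerance = 1e-7)
})

test_that("EM frequencies sum to one and log-likelihood never decreases", {
  cfg <- sim_config(n_individuals = 150, pool_size = 8, miscall = 0,
                    dropout = 0, rna_silencing = 0)
  sim <- simulate_cohort(cfg, seed = 5)
  fit <- em_frequencies(sim$genotypes)
  expect_equal(sum(fit$frequencies$frequency), 1, tolerance = 1e-9)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_true(fit$converged)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n, 150)
})

test_that("most likely diplotype matches exhaustive argmax", {
  set.seed(41)
  ref <- abc_ref()
  for (i in 1:100) {
    g <- random_genotype(loci = c("A", "B", "C"), n_alleles = 4)
    top <- most_likely_diplotype(g, ref)
    # independent argmax over the enumerated pairs
    oracle_pairs <- strsplit(brute_diplotypes(g), "||", fixed = TRUE)
    score <- function(p) {
      f <- function(h) {
        i <- match(h, ref$haplotype)
        if (is.na(i)) 1e-9 else max(ref$frequency[i], 1e-9)
      }
      f(p[1]) * f(p[2]) * if (p[1] == p[2]) 1 else 2
    }
    scores <- vapply(oracle_pairs, score, 1.0)
    expect_equal(top$score[1], max(scores))
    best <- oracle_pairs[scores == max(scores)]
    expect_true(any(vapply(best, function(p)
      identical(p, c(top$hap1[1], top$hap2[1])), TRUE)))
  }
})

test_that("constructed frequency ratios rank diplotypes as expected", {
  ref <- tibble::tibble(
    label = as.character(1:4),
    haplotype = c("A*01:01~B*07:02", "A*02:01~B*08:01",
                  "A*01:01~B*08:01", "A*02:01~B*07:02"),
    frequency = c(0.1, 0.2, 0.01, 0.01))
  g <- tibble::tibble(locus = c("A", "B"),
                      allele1 = c("A*01:01", "B*07:02"),
                      allele2 = c("A*02:01", "B*08:01"))
  r <- most_likely_diplotype(g, ref)
  expect_equal(r$hap1[1], "A*01:01~B*07:02")
  expect_equal(r$score[1] / r$score[2], 200)
  # single compatible pair gets probability 1
  hom <- tibble::tibble(locus = c("A", "B"),
                        allele1 = c("A*01:01", "B*07:02"),
                        allele2 = c("A*01:01", "B*07:02"))
  expect_equal(most_likely_diplotype(hom, ref)$prob, 1)
})

test_that("reference haplotypes classify as known; perturbations as variant/unknown", {
  ref <- abc_ref()
  g <- read_g_group_table()
  cls <- classify_haplotypes(ref$haplotype, ref, g)
  expect_true(all(cls$class == "known"))
  expect_equal(cls$matched, ref$label)
  # one-locus perturbation names its source reference
  h <- "A*01:01~B*08:01~C*05:01"   # reference 1 with a foreign C allele
  v <- classify_haplotypes(h, ref, g)
  expect_equal(v$class, "variant")
  expect_equal(v$matched, "1")
  expect_equal(v$variant_label, "1b")
  expect_equal(v$divergent_locus, "C")
  # two-locus perturbation from every reference is unknown
  u <- classify_haplotypes("A*98:01~B*98:01~C*07:01", ref, g)
  expect_equal(u$class, "unknown")
})

test_that("variant suffixes advance in discovery order per reference", {
  ref <- abc_ref()
  haps <- c("A*01:01~B*08:01~C*05:01",  # variant of ref 1
            "A*01:01~B*08:01~C*06:02",  # second distinct variant of ref 1
            "A*01:01~B*08:01~C*05:01")  # repeat of the first
  cls <- classify_haplotypes(haps, ref)
  expect_equal(cls$variant_label, c("1b", "1c", "1b"))
})

test_that("G-group-only divergence is a flagged variant", {
  ref <- abc_ref()
  g <- read_g_group_table()
  # reference 6 carries C*07:06; C*07:01 is in the same G group
  h <- "A*23:01~B*49:01~C*07:01"
  cls <- classify_haplotypes(h, ref, g)
  expect_equal(cls$class, "variant")
  expect_true(cls$g_group_flag)
  expect_equal(cls$matched, "6")
})

test_that("empty reference classifies everything unknown with a warning", {
  ref <- abc_ref()[0, ]
  expect_warning(cls <- classify_haplotypes("A*01:01~B*08:01~C*07:01", ref),
                 "empty reference")
  expect_equal(cls$class, "unknown")
})

test_that("DRB1 allele groups resolve to DRB3/4/5 combinations", {
  r <- resolve_drb345(
    c("DRB1*03:01", "DRB1*01:01", "DRB1*15:01", "DRB1*04:01"),
    c("DRB1*07:01", "DRB1*01:02", "DRB1*16:01", "DRB1*08:01"))
  expect_equal(r$combination,
               c("DRB1-DRB3/DRB1-DRB4",  # DR52 + DR53
                 "DRB1/DRB1",            # DR1 carries no paralogue
                 "DRB1-DRB5/DRB1-DRB5",  # both DR51
                 "DRB1/DRB1-DRB4"))      # DR53 + DR8
  expect_true(all(r$resolved))
  # missing linkage entry flags unresolved instead of erroring
  miss <- resolve_drb345("DRB1*99:01", "DRB1*03:01")
  expect_false(miss$resolved)
  expect_true(is.na(miss$combination))
})

test_that("reference reader builds haplotype strings and reports coverage", {
  expect_message(
    ref <- read_haplotype_frequencies(
      system.file("extdata", "reference_haplotypes_abc_synthetic.tsv",
                  package = "hlacohort")),
    "chromosome mass")
  expect_equal(attr(ref, "loci"), c("A", "B", "C"))
  expect_equal(ref$haplotype[1], "A*01:01~B*08:01~C*07:01")
})
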