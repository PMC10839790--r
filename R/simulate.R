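# Derive a per-stream sub-seed from the top-level seed so each generator
# stage is independently reproducible. Kept below 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483647
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a pediatric pan-cancer immunogenetics cohort: several
#' hundred patients typed by multiple algorithms from normal WES, tumor
#' WES and tumor RNA-seq; small per-call miscall and allele-dropout
#' probabilities mirroring the >99% per-tool accuracy regime; and a
#' transcript-silencing probability producing the RNA-specific loss of
#' allele detection seen in some tumors.
#'
#' @param n_individuals Number of patients.
#' @param loci Locus set carried by the simulated haplotypes.
#' @param pool_size Number of founder haplotypes in the population pool.
#' @param concentration Dirichlet concentration for the pool frequencies.
#' @param miscall Per-call probability that one allele is replaced by a
#'   different pool allele of the same locus.
#' @param dropout Per-call probability that only one allele is reported
#'   (a putative homozygote).
#' @param rna_silencing Per-(individual, locus) probability that one
#'   chromosome's transcript is silenced, so RNA-based calls see a single
#'   allele. Either a scalar or one probability per locus.
#' @param include_fallback Emit calls from the stage-2 fallback
#'   algorithms (run on normal WES) in addition to the two primary tools.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 576, loci = c("A", "B", "C"),
                       pool_size = 20, concentration = 1,
                       miscall = 0.01, dropout = 0.01,
                       rna_silencing = 0.02, include_fallback = TRUE) {
  stopifnot(n_individuals >= 1, pool_size >= 2,
            all(c(miscall, dropout, rna_silencing) >= 0),
            all(c(miscall, dropout, rna_silencing) <= 1),
            length(rna_silencing) %in% c(1L, length(loci)))
  structure(list(
    n_individuals = n_individuals, loci = loci, pool_size = pool_size,
    concentration = concentration, miscall = miscall, dropout = dropout,
    rna_silencing = rna_silencing, include_fallback = include_fallback
  ), class = "sim_config")
}

rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  g / sum(g)
}

# Draw a pool of distinct multilocus haplotypes with Dirichlet frequencies.
draw_haplotype_pool <- function(cfg) {
  K <- cfg$pool_size
  # per-locus allele universes: allele groups 1..K with small protein numbers
  universes <- lapply(cfg$loci, function(l) {
    render_allele(locus = l, field1 = seq_len(K),
                  field2 = sample.int(50, K, replace = TRUE),
                  suffix = rep(NA_character_, K))
  })
  repeat {
    haps <- do.call(haplotype_string,
                    lapply(universes, function(u) sample(u, K, replace = TRUE)))
    if (!anyDuplicated(haps)) break
  }
  tibble(haplotype = haps, frequency = rdirichlet1(K, cfg$concentration))
}

# Which algorithms type which samples; `rna` marks RNA-based evidence
# subject to transcript silencing.
sim_algorithm_table <- function(cfg) {
  base <- tibble(
    algorithm = c("HLA-HD", "HLA-HD", "HLA-HD", "HLAProfiler"),
    sample_kind = c("normal-WES", "tumor-WES", "tumor-RNA", "tumor-RNA"),
    rna = c(FALSE, FALSE, TRUE, TRUE)
  )
  if (cfg$include_fallback) {
    base <- bind_rows(base, tibble(
      algorithm = c("Optitype", "xHLA", "HISAT-genotype"),
      sample_kind = "normal-WES", rna = FALSE
    ))
  }
  base
}

#' Simulate a typed cohort with known diplotypes
#'
#' Draws pool haplotype frequencies from a Dirichlet distribution, forms
#' individuals by two independent haplotype draws (random mating), and
#' emits per-(algorithm, sample) genotype calls corrupted by miscall,
#' dropout and RNA transcript-silencing noise.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `truth` (tibble `patient`, `hap1`, `hap2`), `pool`
#'   (haplotype frequencies), `genotypes` (noise-free long genotype
#'   table) and `calls` (typing-call table for [patient_consensus()]).
#' @export
simulate_cohort <- function(cfg = sim_config(), seed = 1) {
  set.seed(derive_seed(seed, 1))
  pool <- draw_haplotype_pool(cfg)
  N <- cfg$n_individuals
  pick <- function() sample(pool$haplotype, N, replace = TRUE,
                            prob = pool$frequency)
  truth <- tibble(
    patient = sprintf("P%04d", seq_len(N)),
    hap1 = pick(), hap2 = pick()
  )
  genotypes <- truth_genotypes(truth, cfg$loci)
  # per-(individual, locus) transcript silencing: 0 = none, 1/2 = that
  # chromosome's allele is invisible to RNA-based callers
  p_sil <- rep_len(cfg$rna_silencing, length(cfg$loci))
  silenced <- matrix(
    ifelse(stats::runif(N * length(cfg$loci)) <
             rep(p_sil, each = N),
           sample(1:2, N * length(cfg$loci), replace = TRUE), 0L),
    nrow = N
  )
  algos <- sim_algorithm_table(cfg)
  hap_mat1 <- do.call(rbind, split_haplotype(truth$hap1))
  hap_mat2 <- do.call(rbind, split_haplotype(truth$hap2))
  locus_universe <- lapply(seq_along(cfg$loci), function(j) {
    unique(c(hap_mat1[, j], hap_mat2[, j]))
  })
  calls <- purrr::pmap(algos, function(algorithm, sample_kind, rna) {
    rows <- purrr::map(seq_len(N), function(i) {
      a1 <- hap_mat1[i, ]; a2 <- hap_mat2[i, ]
      single <- rep(FALSE, length(cfg$loci))
      for (j in seq_along(cfg$loci)) {
        if (rna && silenced[i, j] > 0) {
          if (silenced[i, j] == 1L) a1[j] <- a2[j] else a2[j] <- a1[j]
          single[j] <- TRUE
        }
        if (stats::runif(1) < cfg$miscall) {
          u <- setdiff(locus_universe[[j]], c(a1[j], a2[j]))
          if (length(u) > 0) {
            if (stats::runif(1) < 0.5) a1[j] <- sample(u, 1)
            else a2[j] <- sample(u, 1)
          }
        }
        if (!single[j] && stats::runif(1) < cfg$dropout) {
          if (stats::runif(1) < 0.5) a2[j] <- a1[j] else a1[j] <- a2[j]
          single[j] <- TRUE
        }
      }
      hom <- a1 == a2
      tibble(patient = truth$patient[i],
             sample = paste(truth$patient[i], sample_kind, sep = "-"),
             material = sample_kind, algorithm = algorithm,
             locus = cfg$loci, allele1 = pmin(a1, a2),
             allele2 = ifelse(single | hom, ifelse(single, NA, pmax(a1, a2)),
                              pmax(a1, a2)))
    })
    bind_rows(rows)
  }) |> bind_rows()
  list(truth = truth, pool = pool, genotypes = genotypes, calls = calls)
}

#' Long genotype table from true diplotypes
#'
#' @param truth Tibble with `patient`, `hap1`, `hap2`.
#' @param loci Locus order of the haplotype strings.
#' @return Tibble `patient`, `locus`, `allele1`, `allele2` (alleles
#'   sorted within locus).
#' @export
truth_genotypes <- function(truth, loci) {
  h1 <- do.call(rbind, split_haplotype(truth$hap1))
  h2 <- do.call(rbind, split_haplotype(truth$hap2))
  purrr::map_dfr(seq_along(loci), function(j) {
    tibble(patient = truth$patient, locus = loci[j],
           allele1 = pmin(h1[, j], h2[, j]),
           allele2 = pmax(h1[, j], h2[, j]))
  }) |> arrange(.data$patient)
}

# Representative (CNt, A, B) for each planted category, given ploidy.
category_cn_state <- function(category, ploidy) {
  thr <- amplification_threshold(ploidy)
  switch(category,
    "biallelic-loss" = c(0L, 0L, 0L),
    "LOH" = c(1L, 1L, 0L),
    "CN-LOH" = c(2L, 2L, 0L),
    "LOH+gain" = c(3L, 3L, 0L),
    "LOH+amplification" = c(as.integer(thr), as.integer(thr), 0L),
    "none" = c(2L, 1L, 1L),
    stop("unknown planted category: ", category, call. = FALSE)
  )
}

#' Default segment-planting plan
#'
#' One event of every category over the bundled gene annotation, with
#' sizes straddling the 50 kb retention filter and one sample below the
#' cellularity gate.
#'
#' @param genes Gene annotation tibble.
#' @return Tibble `sample`, `gene`, `category`, `size`, `cellularity`,
#'   `ploidy`.
#' @export
default_segment_plan <- function(genes = read_gene_annotation()) {
  pick <- function(role) genes$gene[genes$role == role][1]
  tibble(
    sample = sprintf("T%02d", 1:8),
    gene = c(pick("HLA-classI"), pick("HLA-classI"), pick("HLA-classII"),
             pick("HLA-classI"), pick("B2M"), pick("CIITA"),
             pick("HLA-classI"), pick("HLA-classI")),
    category = c("LOH", "CN-LOH", "LOH+gain", "LOH+amplification",
                 "biallelic-loss", "LOH", "LOH", "LOH"),
    size = c(200e3, 200e3, 200e3, 200e3, 100e3, 100e3, 45e3, 200e3),
    cellularity = c(rep(0.6, 7), 0.15),
    ploidy = c(2, 2, 2, 3, 2, 2, 2, 2)
  )
}

#' Simulate allele-specific copy-number segments with planted events
#'
#' @param plan Event plan as in [default_segment_plan()].
#' @param genes Gene annotation tibble naming the planted intervals.
#' @param seed Integer seed.
#' @param jitter Maximal uniform jitter (bases) applied to segment
#'   placement around the gene midpoint.
#' @return List with `truth` (the plan with planted coordinates),
#'   `segments` and `profiles` tibbles.
#' @export
simulate_segments <- function(plan = default_segment_plan(),
                              genes = read_gene_annotation(), seed = 1,
                              jitter = 1000) {
  set.seed(derive_seed(seed, 2))
  idx <- match(plan$gene, genes$gene)
  if (anyNA(idx)) {
    stop("segment plan references unknown gene(s): ",
         paste(unique(plan$gene[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  mid <- (genes$start[idx] + genes$end[idx]) %/% 2
  start <- pmax(1, mid - plan$size %/% 2 +
                  as.integer(stats::runif(nrow(plan), -jitter, jitter)))
  state <- t(mapply(category_cn_state, plan$category, plan$ploidy,
                    USE.NAMES = FALSE))
  segments <- tibble(
    sample = plan$sample,
    chromosome = genes$chromosome[idx],
    start = start,
    end = start + as.integer(plan$size) - 1L,
    CNt = state[, 1], A = state[, 2], B = state[, 3]
  )
  profiles <- plan |>
    distinct(.data$sample, .data$cellularity, .data$ploidy)
  truth <- bind_cols(plan, segments[c("chromosome", "start", "end")])
  list(truth = truth, segments = segments, profiles = profiles)
}

#' Default variant-planting plan
#'
#' Deliberately includes borderline records near every filter threshold.
#'
#' @param n_random Number of additional random records appended.
#' @return Tibble `sample`, `gene`, `consequence`, `depth_n`, `vaf_n`,
#'   `depth_t`, `vaf_t`.
#' @export
default_variant_plan <- function(n_random = 50) {
  border <- tibble(
    sample = sprintf("T%02d", rep(1:4, each = 2)),
    gene = rep(c("TAP1", "B2M", "HLA-A", "TAP2"), 2),
    consequence = rep(c("missense", "nonsense", "frameshift", "silent"), 2),
    depth_n = 60, vaf_n = rep(c(0.0, 0.05), 4),
    depth_t = 60, vaf_t = rep(c(0.5, 0.16), 4)
  )
  rand <- tibble(
    sample = sprintf("T%02d", sample.int(10, n_random, replace = TRUE)),
    gene = sample(c("HLA-A", "HLA-B", "B2M", "TAP1", "TAP2", "PSMB8",
                    "OUTSIDE1"), n_random, replace = TRUE),
    consequence = sample(c("missense", "nonsense", "silent", "splice-site"),
                         n_random, replace = TRUE),
    depth_n = sample(30:120, n_random, replace = TRUE),
    vaf_n = stats::runif(n_random, 0, 0.12),
    depth_t = sample(30:120, n_random, replace = TRUE),
    vaf_t = stats::runif(n_random, 0, 0.6)
  )
  bind_rows(border, rand)
}

#' Simulate tumor/normal variant records with binomial read counts
#'
#' @param plan Variant plan as in [default_variant_plan()] (call it
#'   inside a seeded context for reproducible random plans).
#' @param seed Integer seed.
#' @param thresholds Filter thresholds used to label the expected truth.
#' @return List with `truth` (plan plus `expected_pass`, the filter
#'   verdict on the planted expectations) and `records` (observable
#'   table with binomial alt counts and realized VAFs).
#' @export
simulate_variants <- function(plan = NULL, seed = 1,
                              thresholds = somatic_thresholds()) {
  set.seed(derive_seed(seed, 3))
  if (is.null(plan)) plan <- default_variant_plan()
  n_alt <- stats::rbinom(nrow(plan), plan$depth_n, plan$vaf_n)
  t_alt <- stats::rbinom(nrow(plan), plan$depth_t, plan$vaf_t)
  records <- tibble(
    sample = plan$sample, gene = plan$gene,
    consequence = plan$consequence,
    n_alt = n_alt, n_vaf = n_alt / plan$depth_n,
    t_alt = t_alt, t_vaf = t_alt / plan$depth_t,
    qual_pass = TRUE
  )
  exp_n_alt <- plan$depth_n * plan$vaf_n
  exp_t_alt <- plan$depth_t * plan$vaf_t
  truth <- plan
  truth$expected_pass <-
    exp_n_alt < thresholds$normal_max_reads &
    plan$vaf_n < thresholds$normal_max_vaf &
    exp_t_alt > thresholds$tumor_min_reads &
    plan$vaf_t >= thresholds$tumor_min_vaf
  list(truth = truth, records = records)
}

#' Simulate a qPCR Ct table with known true quantities
#'
#' Reference assays amplify at a common baseline cycle; a target with
#' true relative quantity q amplifies at baseline - log2(q). Gaussian
#' cycle noise is added independently to every replicate well.
#'
#' @param plan Tibble `sample`, `assay`, `true_quantity`; defaults to a
#'   small grid of quantities spanning four orders of magnitude.
#' @param reference_assays Names of the reference (housekeeping) assays.
#' @param baseline Reference amplification cycle.
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param n_replicates Replicate wells per (sample, assay).
#' @param seed Integer seed.
#' @return List with `truth` (the plan) and `ct` (tibble `sample`,
#'   `assay`, `ct_rep1..k`, `ct` mean).
#' @export
simulate_expression <- function(plan = NULL,
                                reference_assays = paste0("REF", 1:5),
                                baseline = 20, noise_sd = 0.1,
                                n_replicates = 2, seed = 1) {
  set.seed(derive_seed(seed, 4))
  if (is.null(plan)) {
    plan <- tidyr::expand_grid(
      sample = sprintf("X%02d", 1:6),
      assay = c("HLA-A", "HLA-B", "TAP1")
    )
    plan$true_quantity <- 2^stats::runif(nrow(plan), -7, 3)
  }
  targets <- plan |>
    mutate(true_ct = baseline - log2(.data$true_quantity))
  refs <- tidyr::expand_grid(sample = unique(plan$sample),
                             assay = reference_assays)
  refs$true_ct <- baseline
  refs$true_quantity <- NA_real_
  all_rows <- bind_rows(targets, refs)
  for (k in seq_len(n_replicates)) {
    all_rows[[paste0("ct_rep", k)]] <-
      all_rows$true_ct + stats::rnorm(nrow(all_rows), 0, noise_sd)
  }
  reps <- as.matrix(all_rows[paste0("ct_rep", seq_len(n_replicates))])
  ct <- all_rows |>
    mutate(ct = rowMeans(reps)) |>
    select("sample", "assay", dplyr::starts_with("ct_rep"), "ct")
  list(truth = plan, ct = ct)
}
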