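#' Pipeline run configuration
#'
#' Collects input tables (or paths), fixture overrides and thresholds for
#' [run_pipeline()]. Any input left NULL is produced by the synthetic
#' generator when the `simulate` stage is selected; a stage whose input
#' is missing otherwise raises a dependency error naming it.
#'
#' @param out_dir Output directory for stage TSVs and the run manifest.
#' @param seed Integer seed for the simulation stages.
#' @param sim A [sim_config()] for the simulate stage.
#' @param calls,segments,profiles,variants,ct Optional input tibbles (or
#'   TSV paths) for the respective stages.
#' @param genes,arms Gene/arm annotation tibbles (bundled defaults).
#' @param reference_haplotypes Optional reference haplotype table for
#'   classification ([read_haplotype_frequencies()]).
#' @param controls Optional control allele-frequency table for screening.
#' @param policy Consensus policy; `thresholds` somatic thresholds.
#' @param min_segment_size,min_cellularity Segment retention gates.
#' @param reference_assays qPCR reference assays.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("hlacohort-run-"), seed = 1,
                       sim = sim_config(n_individuals = 100),
                       calls = NULL, segments = NULL, profiles = NULL,
                       variants = NULL, ct = NULL,
                       genes = read_gene_annotation(),
                       arms = read_arm_definitions(),
                       reference_haplotypes = NULL, controls = NULL,
                       policy = consensus_policy(),
                       thresholds = somatic_thresholds(),
                       min_segment_size = 50000, min_cellularity = 0.2,
                       reference_assays = paste0("REF", 1:5)) {
  structure(as.list(environment()), class = "run_config")
}

load_if_path <- function(x, reader) {
  if (is.character(x) && length(x) == 1) reader(x) else x
}

require_input <- function(x, stage, name) {
  if (is.null(x)) {
    stop(sprintf("stage '%s' requires input '%s'; run the simulate stage or supply it",
                 stage, name), call. = FALSE)
  }
  x
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order (consensus before
#' haplotype and cohort statistics; segment loading before LOH), writes
#' one TSV per stage plus a JSON run manifest recording the seed,
#' thresholds and output digests, and returns the stage results.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "consensus", "haplotype",
#'   "cohort-stats", "loh", "somatic", "qpcr")`.
#' @return Invisibly, a named list of stage result tables; side effect:
#'   TSV/JSON files under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "consensus", "haplotype",
                                    "cohort-stats", "loh", "somatic",
                                    "qpcr")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  emit <- function(name, tab) {
    readr::write_tsv(tab, file.path(config$out_dir, paste0(name, ".tsv")))
    results[[name]] <<- tab
  }
  calls <- load_if_path(config$calls, function(p)
    readr::read_tsv(p, col_types = readr::cols(), progress = FALSE))
  segments <- load_if_path(config$segments, read_segments)
  profiles <- load_if_path(config$profiles, read_sample_profiles)
  variants <- load_if_path(config$variants, function(p)
    readr::read_tsv(p, col_types = readr::cols(), progress = FALSE))
  ct <- load_if_path(config$ct, read_ct_table)
  pool <- NULL
  if ("simulate" %in% stages) {
    sim <- simulate_cohort(config$sim, config$seed)
    seg <- simulate_segments(seed = config$seed, genes = config$genes)
    var <- simulate_variants(seed = config$seed)
    expr <- simulate_expression(seed = config$seed,
                                reference_assays = config$reference_assays)
    calls <- calls %||% sim$calls
    segments <- segments %||% seg$segments
    profiles <- profiles %||% seg$profiles
    variants <- variants %||% var$records
    ct <- ct %||% expr$ct
    pool <- sim$pool
    emit("sim_truth_diplotypes", sim$truth)
    emit("sim_truth_pool", sim$pool)
    emit("sim_calls", sim$calls)
    emit("sim_segments", seg$segments)
    emit("sim_variants", var$records)
  }
  consensus <- NULL
  if ("consensus" %in% stages) {
    calls <- require_input(calls, "consensus", "calls")
    consensus <- patient_consensus(calls, config$policy)
    emit("consensus", consensus)
    emit("completeness", consensus_completeness(
      consensus, loci = unique(calls$locus)))
  }
  if ("haplotype" %in% stages) {
    consensus <- require_input(consensus, "haplotype", "consensus")
    ok <- consensus[consensus$status == "consensus", , drop = FALSE]
    loci <- unique(ok$locus)
    fit <- em_frequencies(ok[c("patient", "locus", "allele1", "allele2")],
                          loci = loci)
    emit("haplotype_frequencies", tidy(fit))
    ref <- config$reference_haplotypes
    if (is.null(ref)) {
      ref <- tidy(fit)
      ref$label <- as.character(seq_len(nrow(ref)))
      attr(ref, "loci") <- loci
    }
    assign <- ok |>
      group_by(.data$patient) |>
      group_modify(~ most_likely_diplotype(.x, ref, loci = loci)[1, ]) |>
      ungroup()
    cls <- classify_haplotypes(unique(c(assign$hap1, assign$hap2)), ref)
    emit("diplotypes", assign)
    emit("haplotype_classes", cls)
  }
  if ("cohort-stats" %in% stages) {
    consensus <- require_input(consensus, "cohort-stats", "consensus")
    freqs <- bind_rows(lapply(unique(consensus$locus), function(l)
      allele_frequencies(consensus, l)))
    emit("allele_frequencies", freqs)
    emit("homozygosity", homozygosity_rates(consensus))
    if (!is.null(config$controls)) {
      scr <- bind_rows(lapply(unique(config$controls$locus), function(l) {
        s <- screen_alleles(freqs[freqs$locus == l, ],
                            config$controls[config$controls$locus == l, ])
        s$locus <- l
        s
      }))
      emit("screening", scr)
    }
  }
  if ("loh" %in% stages) {
    segments <- require_input(segments, "loh", "segments")
    profiles <- require_input(profiles, "loh", "profiles")
    kept <- load_segments(segments, profiles, config$genes,
                          min_size = config$min_segment_size,
                          min_cellularity = config$min_cellularity)
    classified <- classify_segments(kept$retained, profiles)
    ev <- gene_events(classified, config$genes)
    ev$patient <- ev$sample
    emit("segment_rejections", kept$rejected)
    emit("gene_events", ev)
    emit("loh_prevalence",
         loh_prevalence(ev, patients = unique(profiles$sample[
           profiles$cellularity >= config$min_cellularity])))
  }
  if ("somatic" %in% stages) {
    variants <- require_input(variants, "somatic", "variants")
    flt <- variant_passes(variants, config$thresholds)
    emit("somatic_filtered", flt)
    emit("somatic_summary", summarize_somatic(flt, read_gene_set()))
  }
  if ("qpcr" %in% stages) {
    ct <- require_input(ct, "qpcr", "ct")
    emit("expression", quantify_expression(ct, config$reference_assays))
  }
  files <- list.files(config$out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest <- list(
    package = "hlacohort",
    version = as.character(utils::packageVersion("hlacohort")),
    seed = config$seed,
    stages = stages,
    thresholds = config$thresholds,
    min_segment_size = config$min_segment_size,
    min_cellularity = config$min_cellularity,
    outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                      basename(files)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
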