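#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample`, `assay` and one or more
#'   replicate columns `ct_rep1`, `ct_rep2`, ... Undetermined wells are
#'   empty or `NA`.
#' @return Tibble with `sample`, `assay`, the replicate columns and
#'   `ct` (arithmetic mean of the available replicate cycles; `NA` when
#'   all replicates are undetermined).
#' @export
read_ct_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE,
                         na = c("", "NA", "Undetermined"))
  stopifnot(all(c("sample", "assay") %in% names(tab)))
  reps <- grep("^ct_rep", names(tab), value = TRUE)
  stopifnot(length(reps) >= 1)
  m <- as.matrix(tab[reps])
  if (any(m <= 0, na.rm = TRUE)) stop("Ct values must be positive",
                                      call. = FALSE)
  tab$ct <- rowMeans(m, na.rm = TRUE)
  tab$ct[is.nan(tab$ct)] <- NA_real_
  as_tibble(tab)
}

#' Relative transcript quantity by the 2^dCt method
#'
#' Normalizes a target Ct against a set of reference (housekeeping)
#' genes: quantity = 2^(mean(reference Cts) - target Ct). Averaging the
#' reference Cts on the cycle scale is mathematically identical to taking
#' the geometric mean of the per-reference 2^dCt quantities.
#'
#' @param target_ct Numeric vector of target Ct values (cycles). `NA`
#'   (undetermined) propagates to an `NA` quantity, never zero.
#' @param reference_cts Numeric vector of reference-gene Ct values for
#'   the same sample, or a list of such vectors (one per element of
#'   `target_ct`).
#' @return Numeric vector of relative quantities (arbitrary units; 1 when
#'   the target amplifies at the reference mean).
#' @examples
#' relative_quantity(22, c(20, 20, 20, 20, 20))  # 0.25
#' @export
relative_quantity <- function(target_ct, reference_cts) {
  if (!is.list(reference_cts)) {
    reference_cts <- rep(list(reference_cts), length(target_ct))
  }
  stopifnot(length(reference_cts) == length(target_ct),
            all(lengths(reference_cts) >= 1))
  ref_mean <- vapply(reference_cts, mean, 1.0)
  2^(ref_mean - target_ct)
}

#' Per-sample relative quantities for a Ct table
#'
#' @param ct_table Tibble from [read_ct_table()] (columns `sample`,
#'   `assay`, `ct`).
#' @param reference_assays Character vector naming the reference
#'   (housekeeping) assays; their per-sample mean Ct normalizes every
#'   other assay.
#' @return Tibble with `sample`, `assay`, `ct`, `ref_ct` and `quantity`
#'   for all non-reference assays.
#' @export
quantify_expression <- function(ct_table, reference_assays) {
  stopifnot(length(reference_assays) >= 1)
  refs <- ct_table |>
    filter(.data$assay %in% reference_assays, !is.na(.data$ct)) |>
    group_by(.data$sample) |>
    summarise(ref_ct = mean(.data$ct), n_refs = n(), .groups = "drop")
  ct_table |>
    filter(!.data$assay %in% reference_assays) |>
    inner_join(refs, by = "sample") |>
    mutate(quantity = 2^(.data$ref_ct - .data$ct)) |>
    select("sample", "assay", "ct", "ref_ct", "n_refs", "quantity")
}

#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against log10 of the known input quantity over
#' a dilution series; the amplification efficiency is
#' 10^(-1/slope) - 1 (1.0 for perfect doubling chemistry, slope
#' -1/log10(2) = -3.32 cycles per decade).
#'
#' @param quantity Known input quantities (e.g. ng of cDNA), at least 3
#'   distinct positive values.
#' @param ct Observed Ct per dilution point.
#' @return An object of class `standard_curve` with the fitted `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `n` and the underlying `lm`
#'   fit. [tidy.standard_curve()] and [glance.standard_curve()] extract
#'   results.
#' @examples
#' fit_standard_curve(9 / 5^(0:5), 20 + log2(5) * (0:5))
#' @export
fit_standard_curve <- function(quantity, ct) {
  stopifnot(length(quantity) == length(ct), length(quantity) >= 3,
            all(quantity > 0))
  if (length(unique(quantity)) < 2) {
    stop("degenerate dilution series: all quantities equal", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10(quantity))
  slope <- unname(stats::coef(fit)[2])
  out <- list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    efficiency = 10^(-1 / slope) - 1,
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = length(ct),
    points = tibble(quantity = quantity, ct = ct),
    fit = fit
  )
  class(out) <- "standard_curve"
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "qPCR standard curve: slope %.4f cycles/decade, efficiency %.1f%%, R^2 %.4f (n = %d)\n",
    x$slope, 100 * x$efficiency, x$r_squared, x$n))
  invisible(x)
}

#' Tidy a standard-curve fit
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Tibble with `term` and `estimate` for intercept and slope.
#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' One-row summary of a standard-curve fit
#'
#' @param x A `standard_curve` object.
#' @param ... Unused.
#' @return Tibble with `slope`, `efficiency`, `r_squared`, `n`.
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, efficiency = x$efficiency,
         r_squared = x$r_squared, n = x$n)
}
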