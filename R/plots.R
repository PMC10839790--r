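#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_col geom_abline
#'   geom_hline labs scale_y_log10 theme_minimal
NULL

#' Bubble plot of an allele-screening result
#'
#' Patient frequency against the patient/control frequency ratio, sized
#' by control frequency and colored by screening flag; the horizontal
#' guides mark the ratio bounds of the screening criteria.
#'
#' @param object A tibble from [screen_alleles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hla_screen
#' @export
autoplot.hla_screen <- function(object, ...) {
  flagged <- object[!is.na(object$ratio), , drop = FALSE]
  ggplot(flagged, aes(x = .data$freq_patients, y = .data$ratio,
                      size = .data$freq_controls, color = .data$flag)) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = c(0.5, 0.67, 1.5, 2), linetype = "dashed",
               linewidth = 0.3) +
    scale_y_log10() +
    labs(x = "allele frequency in patients",
         y = "frequency ratio (patients / controls)",
         size = "control freq.", color = NULL) +
    theme_minimal()
}

#' Haplotype-frequency bar plot for an EM fit
#'
#' @param object An `hla_em` object.
#' @param n Number of top haplotypes shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hla_em
#' @export
autoplot.hla_em <- function(object, n = 20, ...) {
  top <- utils::head(object$frequencies, n)
  top$haplotype <- factor(top$haplotype, levels = rev(top$haplotype))
  ggplot(top, aes(x = .data$frequency, y = .data$haplotype)) +
    geom_col() +
    labs(x = "estimated haplotype frequency", y = NULL) +
    theme_minimal()
}

#' Standard-curve plot
#'
#' Observed Ct against log10 input quantity with the fitted line.
#'
#' @param object A `standard_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot standard_curve
#' @export
autoplot.standard_curve <- function(object, ...) {
  ggplot(object$points, aes(x = log10(.data$quantity), y = .data$ct)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linetype = "dashed") +
    labs(x = "log10 input quantity", y = "Ct (cycles)",
         subtitle = sprintf("slope %.3f, efficiency %.1f%%",
                            object$slope, 100 * object$efficiency)) +
    theme_minimal()
}

#' Bar plot of LOH prevalence per gene
#'
#' @param prevalence Tibble from [loh_prevalence()].
#' @return A ggplot object.
#' @export
plot_loh_prevalence <- function(prevalence) {
  ggplot(prevalence, aes(x = .data$measure, y = 100 * .data$prevalence,
                         fill = .data$qualifying)) +
    geom_col() +
    labs(x = NULL, y = "LOH prevalence (%)", fill = "counted events") +
    theme_minimal()
}
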