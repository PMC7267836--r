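# broom-style tidiers, glances and ggplot2 autoplot methods for the
# package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.riboloop_run <- function(x, ...) {
  cat("<riboloop_run>\n")
  cat("  iterations:", nrow(x$trace), "\n")
  cat("  contigs (pre-filter):", nrow(x$contigs), "\n")
  cat("  final unmapped pairs:",
      if (is.null(x$unmapped)) 0 else nrow(x$unmapped), "\n")
  if (nrow(x$trace) > 0)
    cat("  termination:",
        x$trace$termination_reason[nrow(x$trace)], "\n")
  invisible(x)
}

#' Tidy the per-iteration trace of a reconstruction run
#'
#' @param x A `riboloop_run` object.
#' @param ... Unused.
#' @return The trace tibble (one row per iteration).
#' @method tidy riboloop_run
#' @export
tidy.riboloop_run <- function(x, ...) x$trace

#' One-row summary of a reconstruction run
#'
#' @param x A `riboloop_run` object.
#' @param ... Unused.
#' @return A one-row tibble: iterations, contigs, final_unmapped,
#'   termination_reason.
#' @method glance riboloop_run
#' @export
glance.riboloop_run <- function(x, ...) {
  tibble(iterations = nrow(x$trace),
         contigs = nrow(x$contigs),
         final_unmapped = if (is.null(x$unmapped)) 0L else nrow(x$unmapped),
         termination_reason = if (nrow(x$trace) > 0)
           x$trace$termination_reason[nrow(x$trace)] else NA_character_)
}

#' Plot pool shrinkage and contig growth over iterations
#'
#' @param object A `riboloop_run` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot riboloop_run
#' @export
autoplot.riboloop_run <- function(object, ...) {
  tr <- object$trace
  d <- tidyr::pivot_longer(
    tr[, c("iteration", "unmapped_count", "contig_count")],
    cols = c("unmapped_count", "contig_count"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL,
                  title = "Unmapped pool and contig set per iteration") +
    ggplot2::theme_minimal()
}

#' @export
print.riboloop_result <- function(x, ...) {
  cat("<riboloop_result>\n")
  cat("  kept contigs:", nrow(x$kept), " dropped:", nrow(x$dropped), "\n")
  cat("  samples:", max(0L, ncol(x$abundance) - 1L), "\n")
  print(x$run)
  invisible(x)
}

#' Tidy a pipeline result into a long abundance table
#'
#' @param x A `riboloop_result` object.
#' @param ... Unused.
#' @return A tibble with columns contig_id, sample, abundance.
#' @method tidy riboloop_result
#' @export
tidy.riboloop_result <- function(x, ...) {
  ab <- as_tibble(as.data.frame(unclass(x$abundance), check.names = FALSE))
  if (ncol(ab) <= 1)
    return(tibble(contig_id = character(), sample = character(),
                  abundance = numeric()))
  tidyr::pivot_longer(ab, cols = -"contig_id", names_to = "sample",
                      values_to = "abundance")
}

#' One-row summary of a pipeline result
#'
#' @param x A `riboloop_result` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance riboloop_result
#' @export
glance.riboloop_result <- function(x, ...) {
  g <- glance(x$run)
  g$kept_contigs <- nrow(x$kept)
  g$dropped_contigs <- nrow(x$dropped)
  g
}

#' @export
print.riboloop_eval <- function(x, ...) {
  cat("<riboloop_eval>\n")
  at97 <- x$sweep[abs(x$sweep$threshold - 0.97) < 1e-9, ]
  if (nrow(at97) == 1)
    cat(sprintf("  at 0.97: precision %.3f sensitivity %.3f f1 %.3f\n",
                at97$precision, at97$sensitivity, at97$f1))
  if (!is.null(x$abundance_cor))
    cat(sprintf("  abundance Pearson r: %.3f (n = %d)\n",
                x$abundance_cor$pearson_r, x$abundance_cor$n))
  invisible(x)
}

#' Tidy an evaluation into the threshold sweep
#'
#' @param x A `riboloop_eval` object.
#' @param ... Unused.
#' @return The sweep tibble (threshold, tp, fp, fn, precision,
#'   sensitivity, f1).
#' @method tidy riboloop_eval
#' @export
tidy.riboloop_eval <- function(x, ...) x$sweep

#' One-row evaluation summary at the 0.97 threshold
#'
#' @param x A `riboloop_eval` object.
#' @param ... Unused.
#' @return A one-row tibble with precision/sensitivity/f1 at 0.97 and the
#'   abundance Pearson r (NA when not computed).
#' @method glance riboloop_eval
#' @export
glance.riboloop_eval <- function(x, ...) {
  at97 <- confusion_at(x$matches, 0.97)
  tibble(precision_97 = at97$precision, sensitivity_97 = at97$sensitivity,
         f1_97 = at97$f1,
         pearson_r = if (is.null(x$abundance_cor)) NA_real_
                     else x$abundance_cor$pearson_r)
}

#' Plot the precision/sensitivity/F1 threshold sweep
#'
#' @param object A `riboloop_eval` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot riboloop_eval
#' @export
autoplot.riboloop_eval <- function(object, ...) {
  d <- tidyr::pivot_longer(
    object$sweep[, c("threshold", "precision", "sensitivity", "f1")],
    cols = -"threshold", names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$threshold, y = .data$value,
                                  colour = .data$measure)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "similarity threshold", y = NULL, colour = NULL,
                  title = "Reconstruction quality vs similarity threshold") +
    ggplot2::theme_minimal()
}

#' Plot estimated vs true abundance on log-log axes
#'
#' @param object A `riboloop_abcor` object (see
#'   [abundance_correlation()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot riboloop_abcor
#' @export
autoplot.riboloop_abcor <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$src_ab, y = .data$est_ab,
                               colour = .data$sim)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "true abundance (src_ab)",
                  y = "estimated abundance (est_ab)", colour = "sim",
                  title = sprintf("Abundance recovery (Pearson r = %.3f)",
                                  object$pearson_r)) +
    ggplot2::theme_minimal()
}
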