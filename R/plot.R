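#' Diagram a transcript leader and its annotated ORF events
#'
#' Draws the leader and the start of the main ORF on the HGVS c. axis, marking
#' the sAUG and, for each report row that created or reshaped an upstream ORF,
#' the uAUG, the ORF span and its terminating stop. This is the
#' reading-frame-geometry figure a reviewer would sketch by hand: ORF bars
#' above the axis, colour-coded by predicted consequence.
#'
#' @param model The reference [transcript_model()].
#' @param report Optional report from [annotate_variants()]; rows without a
#'   uAUG are skipped.
#' @return A ggplot object.
#' @examples
#' tx <- build_fixture()
#' rep <- annotate_variants(fixture_variant_sets(), tx)
#' plot_leader(tx, rep)
#' @export
plot_leader <- function(model, report = NULL) {
  stopifnot(inherits(model, "transcript_model"))
  L <- model$utr5_length
  cds_shown <- min(nchar(model$sequence) - L, 60L)
  backbone <- tibble(
    xmin = c(-L, 1), xmax = c(-1, cds_shown),
    region = c("5' UTR (leader)", "CDS (mORF)")
  )
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = backbone,
      ggplot2::aes(x = .data$xmin, xend = .data$xmax, y = 0, yend = 0,
                   linewidth = .data$region)
    ) +
    ggplot2::scale_linewidth_manual(
      values = c("5' UTR (leader)" = 1, "CDS (mORF)" = 3), guide = "none"
    ) +
    ggplot2::annotate("point", x = 1, y = 0, shape = 17, size = 3) +
    ggplot2::annotate("text", x = 1, y = -0.35, label = "sAUG (c.1)", size = 3) +
    ggplot2::labs(x = "HGVS c. position", y = NULL,
                  title = sprintf("Leader geometry of %s", model$id),
                  colour = "classification") +
    ggplot2::scale_y_continuous(limits = c(-0.6, NA), breaks = NULL) +
    ggplot2::theme_minimal()

  if (!is.null(report)) {
    orfs <- dplyr::filter(as_tibble(report), !is.na(.data$uaug_pos))
    if (nrow(orfs) > 0L) {
      orfs <- dplyr::mutate(
        orfs,
        y = dplyr::row_number() * 0.5,
        orf_end = dplyr::case_when(
          !is.na(.data$stop_last) ~ as.numeric(.data$stop_last),
          .default = 1
        )
      )
      p <- p +
        ggplot2::geom_segment(
          data = orfs,
          ggplot2::aes(x = .data$uaug_pos, xend = .data$orf_end,
                       y = .data$y, yend = .data$y,
                       colour = .data$classification),
          linewidth = 2, lineend = "butt"
        ) +
        ggplot2::geom_point(
          data = orfs,
          ggplot2::aes(x = .data$uaug_pos, y = .data$y,
                       colour = .data$classification),
          shape = 17, size = 2.5
        ) +
        ggplot2::geom_text(
          data = orfs,
          ggplot2::aes(x = .data$uaug_pos, y = .data$y + 0.18,
                       label = .data$variants),
          hjust = 0, size = 2.8
        )
    }
  }
  p
}

#' @rdname plot_leader
#' @param object A report from [annotate_variants()] carrying the transcript
#'   in its `"model"` attribute, or pass `model` explicitly via `...`.
#' @param ... For `autoplot`, a `model =` transcript.
#' @method autoplot uorf_report
#' @export
autoplot.uorf_report <- function(object, ..., model = NULL) {
  if (is.null(model)) model <- attr(object, "model")
  if (is.null(model)) {
    abort("Provide the reference transcript: autoplot(report, model = <transcript_model>).")
  }
  plot_leader(model, object)
}
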