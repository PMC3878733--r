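# ggplot2 views of the pipeline's result types

#' Expression scatter between the two conditions
#'
#' Guide-strand (3p) RPM in condition A against condition B, log10
#' axes, with on/off loci pinned to the axes at half the smallest
#' nonzero RPM.
#'
#' @param expression a [profile_loci()] tibble.
#' @return a ggplot object.
#' @export
plot_expression <- function(expression) {
  wide <- expression |>
    dplyr::distinct(.data$locus_id, .data$condition, .data$rpm_3p) |>
    tidyr::pivot_wider(names_from = "condition", values_from = "rpm_3p")
  conds <- setdiff(names(wide), "locus_id")
  floor_rpm <- min(unlist(wide[conds])[unlist(wide[conds]) > 0]) / 2
  wide <- wide |>
    dplyr::mutate(dplyr::across(dplyr::all_of(conds),
                                ~ pmax(.x, floor_rpm)))
  ggplot2::ggplot(wide, ggplot2::aes(
    x = .data[[conds[1]]], y = .data[[conds[2]]],
    label = .data$locus_id)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = paste0("RPM 3p, ", conds[1]),
                  y = paste0("RPM 3p, ", conds[2]),
                  title = "Guide-strand expression") +
    ggplot2::theme_minimal()
}

#' IsomiR class composition per locus
#'
#' @param isomir_table the `table` element of [isomir_profiles()] (or
#'   the bound table from [run_pipeline()]).
#' @param arm which arm to show (default `"3p"`).
#' @return a ggplot object.
#' @export
plot_isomir_classes <- function(isomir_table, arm = "3p") {
  d <- isomir_table[isomir_table$arm == arm, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$locus_id, y = .data$fraction,
                                  fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(x = NULL, y = "fraction of reads",
                  title = paste0("isomiR composition, ", arm, " arm")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Degradome pileup over a target site
#'
#' 5'-end tag counts across a site, highlighting the canonical
#' position paired with miRNA position 10.
#'
#' @param site one row of a [predict_targets()] table.
#' @param tags degradome tag tibble.
#' @param transcript the transcript sequence.
#' @param anchor_len exact-prefix anchor length (default 20).
#' @return a ggplot object.
#' @export
plot_cleavage_pileup <- function(site, tags, transcript, anchor_len = 20) {
  pos5 <- purrr::map_int(tags$seq, function(sq) {
    p <- regexpr(substr(sq, 1, anchor_len), transcript, fixed = TRUE)[1]
    if (p < 0) NA_integer_ else as.integer(p - 1L)
  })
  keep <- !is.na(pos5) & pos5 >= site$start & pos5 < site$end
  pile <- tibble::tibble(pos = pos5[keep], count = tags$count[keep]) |>
    dplyr::count(.data$pos, wt = .data$count, name = "count") |>
    dplyr::mutate(relative = site$end - .data$pos,
                  canonical = .data$relative %in% c(10, 11))
  ggplot2::ggplot(pile, ggplot2::aes(x = .data$pos, y = .data$count,
                                     fill = .data$canonical)) +
    ggplot2::geom_col(show.legend = TRUE) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey40")) +
    ggplot2::labs(x = "transcript position of tag 5' end", y = "tag count",
                  fill = "positions 10-11",
                  title = paste0(site$mirna_id, " site on ",
                                 site$transcript)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_expression
#' @param object a `mirloci_run`.
#' @param ... unused.
#' @export
autoplot.mirloci_run <- function(object, ...) {
  plot_expression(object$expression)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
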