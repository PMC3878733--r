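# two-condition expression profiling: RPM, fold-change, arm ratios,
# antisense quantification

#' Reads-per-million normalisation
#'
#' `count / total_input_reads * 1e6`: the number of reads mapped to an
#' element out of each million library input reads. The denominator is
#' the total number of sequenced reads (with multiplicities, before
#' mapping), which makes values comparable across libraries.
#'
#' @param count read count (vectorised).
#' @param total_input_reads library size.
#' @return RPM value(s).
#' @examples
#' rpm(500, 1e6)
#' @export
rpm <- function(count, total_input_reads) {
  if (any(total_input_reads <= 0)) abort("library size must be positive")
  count / total_input_reads * 1e6
}

#' Fold-change between two RPM values
#'
#' `rpm_a / rpm_b`. When the denominator is zero but the numerator is
#' not, the locus is expressed in one condition only and the result is
#' the flag `"ON_OFF"`; when both are zero it is `"UNDEFINED"`. Returned
#' as character so flags and numbers share one column; use
#' [fold_change_num()] where a numeric is needed.
#'
#' @param rpm_a,rpm_b RPM in the two conditions (vectorised).
#' @return character vector: formatted ratio, `"ON_OFF"` or
#'   `"UNDEFINED"`.
#' @export
fold_change <- function(rpm_a, rpm_b) {
  dplyr::case_when(
    rpm_a == 0 & rpm_b == 0 ~ "UNDEFINED",
    rpm_b == 0 ~ "ON_OFF",
    .default = format(rpm_a / rpm_b, digits = 6, trim = TRUE)
  )
}

#' Numeric fold-change (flags become Inf/NaN)
#' @inheritParams fold_change
#' @return numeric vector; `Inf` for on/off, `NaN` when both are zero.
#' @export
fold_change_num <- function(rpm_a, rpm_b) rpm_a / rpm_b

#' 3p/5p arm ratio
#'
#' Read-count ratio of the guide (3p) to the passenger (5p) arm. A
#' zero 5p count is flagged `NA` (undefined ratio) rather than
#' infinite.
#'
#' @param count_3p,count_5p arm read counts (vectorised).
#' @return numeric vector, `NA` where `count_5p == 0`.
#' @examples
#' arm_ratio(4, 20)    # passenger-dominant: 5p/3p = 5
#' arm_ratio(177, 150)
#' @export
arm_ratio <- function(count_3p, count_5p) {
  dplyr::if_else(count_5p > 0, count_3p / count_5p, NA_real_)
}

#' Assign reads of a locus to mature, loop, or other
#'
#' A read is assigned to a mature miRNA iff its interval lies within
#' the window from 3 nt upstream of the canonical start to 5 nt
#' downstream of the canonical end, on the sense strand - the
#' isomiR window. Reads inside the annotated terminal loop count as
#' loop-derived; anything else on the precursor is `"other"`. The
#' categories partition the sense reads of a precursor.
#'
#' @param alignments alignments on one locus, precursor coordinates
#'   (`prec_start`, `prec_end` columns) or genomic sense-strand
#'   coordinates (`start`, `end`).
#' @param canonical 0-based half-open interval of the canonical mature
#'   in the same coordinates.
#' @param loop optional loop interval; reads fully inside it are
#'   `"loop"`.
#' @param window_up,window_down window flanks (defaults 3 and 5).
#' @return the alignments with an `assignment` column:
#'   `"mature"`, `"loop"` or `"other"`.
#' @export
assign_reads_to_mature <- function(alignments, canonical, loop = NULL,
                                   window_up = 3, window_down = 5) {
  s <- alignments[["prec_start"]] %||% alignments[["start"]]
  e <- alignments[["prec_end"]] %||% alignments[["end"]]
  in_window <- s >= canonical[1] - window_up & e <= canonical[2] + window_down
  in_loop <- if (is.null(loop)) rep(FALSE, length(s)) else
    s >= loop[1] & e <= loop[2]
  alignments$assignment <- dplyr::case_when(
    in_window ~ "mature",
    in_loop ~ "loop",
    .default = "other")
  alignments
}

#' Count antisense reads over a locus
#'
#' Antisense reads are placements overlapping the locus span on the
#' strand opposite the locus. The sense/antisense ratio is flagged
#' `NA` when no antisense read exists.
#'
#' @param locus one locus row (`chrom`, `strand`, `start`, `end`).
#' @param alignments genome alignments of a library (both strands).
#' @return a list with `sense`, `antisense` (summed counts of
#'   overlapping reads per strand) and `ratio` (= sense/antisense).
#' @export
count_antisense <- function(locus, alignments) {
  ov <- alignments$chrom == locus$chrom &
    alignments$start < locus$end & locus$start < alignments$end
  sense <- sum(alignments$count[ov & alignments$strand == locus$strand])
  anti <- sum(alignments$count[ov & alignments$strand != locus$strand])
  list(sense = sense, antisense = anti,
       ratio = if (anti > 0) sense / anti else NA_real_)
}

# per-locus per-condition counts for one library's alignments
profile_one_library <- function(loci, alignments, total_input_reads,
                                condition, window_up = 3, window_down = 5) {
  purrr::map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    ov <- alignments[alignments$chrom == l$chrom &
                       alignments$start < l$end &
                       l$start < alignments$end, ]
    sense <- ov[ov$strand == l$strand, ]
    anat <- annotate_hairpin(list(structure = l$structure))
    loop_g <- if (!is.null(anat$loop)) {
      if (l$strand == "+") c(l$start + anat$loop[1], l$start + anat$loop[2])
      else c(l$end - anat$loop[2], l$end - anat$loop[1])
    }
    arm_counts <- vapply(c("5p", "3p"), function(arm) {
      cs <- l[[paste0("mature_", arm, "_start")]]
      ce <- l[[paste0("mature_", arm, "_end")]]
      if (is.na(cs)) return(0)
      a <- assign_reads_to_mature(sense, c(cs, ce),
                                  window_up = window_up,
                                  window_down = window_down)
      sum(a$count[a$assignment == "mature"])
    }, numeric(1))
    loop_count <- if (!is.null(loop_g)) {
      sum(sense$count[sense$start >= loop_g[1] & sense$end <= loop_g[2]])
    } else 0L
    as_ <- count_antisense(l, ov)
    tibble::tibble(
      locus_id = l$locus_id, condition = condition,
      count_5p = as.integer(arm_counts[["5p"]]),
      count_3p = as.integer(arm_counts[["3p"]]),
      count_loop = as.integer(loop_count),
      count_sense = as.integer(as_$sense),
      count_antisense = as.integer(as_$antisense),
      total_input_reads = total_input_reads,
      rpm_5p = rpm(arm_counts[["5p"]], total_input_reads),
      rpm_3p = rpm(arm_counts[["3p"]], total_input_reads),
      arm_ratio_3p5p = arm_ratio(arm_counts[["3p"]], arm_counts[["5p"]]),
      sense_antisense_ratio = as_$ratio)
  }) |> dplyr::bind_rows()
}

#' Profile locus expression across two conditions
#'
#' For every locus: per-arm read counts inside the isomiR window around
#' each canonical mature, loop-derived and antisense counts, RPM
#' against each library's total input reads, the 3p/5p arm ratio, and
#' the guide-strand fold-change between the two conditions (with the
#' on/off flag when a locus has reads in only one library).
#'
#' @param loci locus tibble from [discover_loci()] / [tidy()].
#' @param reads_a,reads_b collapsed read tibbles for the two
#'   conditions.
#' @param genome genome tibble.
#' @param condition_a,condition_b labels (defaults `"A"`, `"B"`).
#' @param total_a,total_b library input sizes; default to the summed
#'   read counts of each table (mapped and unmapped alike).
#' @param index optional prebuilt genome index.
#' @return a tibble with one row per locus x condition plus fold-change
#'   columns (`fold_change_3p` computed as condition A over condition
#'   B).
#' @export
profile_loci <- function(loci, reads_a, reads_b, genome,
                         condition_a = "A", condition_b = "B",
                         total_a = sum(reads_a$count),
                         total_b = sum(reads_b$count),
                         index = NULL) {
  index <- index %||% build_kmer_index(genome)
  prof <- dplyr::bind_rows(
    profile_one_library(loci, map_reads(reads_a, index), total_a,
                        condition_a),
    profile_one_library(loci, map_reads(reads_b, index), total_b,
                        condition_b))
  fc <- prof |>
    dplyr::select("locus_id", "condition", "rpm_3p", "rpm_5p") |>
    tidyr::pivot_wider(names_from = "condition",
                       values_from = c("rpm_3p", "rpm_5p")) |>
    dplyr::mutate(
      fold_change_3p = fold_change(
        .data[[paste0("rpm_3p_", condition_a)]],
        .data[[paste0("rpm_3p_", condition_b)]]),
      fold_change_3p_num = fold_change_num(
        .data[[paste0("rpm_3p_", condition_a)]],
        .data[[paste0("rpm_3p_", condition_b)]])) |>
    dplyr::select("locus_id", "fold_change_3p", "fold_change_3p_num")
  dplyr::left_join(prof, fc, by = "locus_id")
}
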