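# canonical-anchored isomiR taxonomy: templated length variants,
# non-templated 3' tails, internal substitutions

#' Classify one read against a canonical mature miRNA
#'
#' Anchors the read on the precursor inside the isomiR window (start
#' between 3 nt upstream of the canonical start and the canonical end)
#' and decomposes it into a precursor-templated part plus a 3'
#' non-templated tail using the maximal-templated-prefix rule: among
#' all admissible anchorings, the one with the longest templated prefix
#' (shortest tail) wins; ties prefer the anchor closest to the
#' canonical start. One internal substitution is tolerated only when
#' the tail is empty, so substitutions can never masquerade as
#' non-templated additions. Tail of all A = adenylated, all T (= U) =
#' uridylated, anything else mixed.
#'
#' @param seq read sequence.
#' @param count read count.
#' @param canonical 0-based half-open canonical interval on the
#'   precursor.
#' @param precursor precursor sequence (5' to 3').
#' @param max_tail maximum tail length (default 3).
#' @param window_up,window_down isomiR window flanks (defaults 3, 5).
#' @return a one-row tibble (`seq`, `count`, `offset_5p`,
#'   `offset_3p_templated`, `nta_tail`, `tail_class`,
#'   `internal_mismatches`, `accepted`, `reason`); `accepted = FALSE`
#'   with a reason when the read cannot be anchored within the window.
#' @export
classify_isomir <- function(seq, count, canonical, precursor,
                            max_tail = 3, window_up = 3, window_down = 5) {
  n <- nchar(seq)
  plen <- nchar(precursor)
  pc <- strsplit(precursor, "")[[1]]
  rc <- strsplit(seq, "")[[1]]
  can_len <- canonical[2] - canonical[1]
  reject <- function(reason) tibble::tibble(
    seq = seq, count = count, offset_5p = NA_integer_,
    offset_3p_templated = NA_integer_, nta_tail = NA_character_,
    tail_class = NA_character_, internal_mismatches = NA_integer_,
    accepted = FALSE, reason = reason)

  starts <- (canonical[1] - window_up):(canonical[1] + can_len - 1)
  starts <- starts[starts >= 0]
  best <- NULL
  for (tail_len in 0:min(max_tail, n - 1)) {
    tl <- n - tail_len                       # templated length
    max_mm <- if (tail_len == 0) 1L else 0L
    for (s in starts[order(abs(starts - canonical[1]))]) {
      if (s + tl > plen) next
      # whole read (templated part + tail) must respect the 3' window
      if (s + n > canonical[2] + window_down) next
      tmpl <- pc[(s + 1):(s + tl)]
      mm <- which(tmpl != rc[1:tl])
      if (length(mm) > max_mm) next
      # a mismatch on the read's final base is a non-templated addition,
      # never an internal substitution; defer to the tailed decomposition
      if (tail_len == 0 && any(mm == tl)) next
      tail <- if (tail_len > 0) rc[(tl + 1):n] else character(0)
      # non-templatedness is literal: every tail base must differ from
      # the template at its position (or fall off the precursor end)
      tail_pos <- s + tl + seq_along(tail)   # 1-based precursor positions
      templated_tail <- tail_pos <= plen & pc[pmin(tail_pos, plen)] == tail
      if (any(templated_tail)) next
      best <- list(s = s, tl = tl, mm = mm, tail = tail)
      break
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(reject("no anchoring within the isomiR window"))
  tail_class <- if (length(best$tail) == 0) "none"
  else if (all(best$tail == "A")) "adenylated"
  else if (all(best$tail == "T")) "uridylated"
  else "mixed"
  tibble::tibble(
    seq = seq, count = count,
    offset_5p = as.integer(best$s - canonical[1]),
    offset_3p_templated = as.integer((best$s + best$tl) - canonical[2]),
    nta_tail = paste(best$tail, collapse = ""),
    tail_class = tail_class,
    internal_mismatches = length(best$mm),
    accepted = TRUE, reason = NA_character_)
}

#' Classify all reads assigned to one canonical mature
#'
#' @param reads tibble with `seq`, `count` (reads already assigned to
#'   this mature by the isomiR window, or carrying non-templated tails
#'   that keep them off the genome).
#' @inheritParams classify_isomir
#' @return tibble of [classify_isomir()] rows, one per read.
#' @export
classify_isomirs <- function(reads, canonical, precursor, max_tail = 3,
                             window_up = 3, window_down = 5) {
  purrr::map2(reads$seq, reads$count, classify_isomir,
              canonical = canonical, precursor = precursor,
              max_tail = max_tail, window_up = window_up,
              window_down = window_down) |>
    dplyr::bind_rows()
}

#' Tabulate isomiR class fractions
#'
#' Partitions the accepted records of one canonical into canonical
#' reads, templated length variants (one cell per
#' `(offset_5p, offset_3p)` pair), and tailed classes (adenylated /
#' uridylated / mixed); fractions are count-weighted and sum to 1 over
#' the partition.
#'
#' @param records output of [classify_isomirs()] for one canonical.
#' @return tibble with `class`, `offset_5p`, `offset_3p`, `count`,
#'   `fraction`.
#' @export
tabulate_isomirs <- function(records) {
  rec <- records[records$accepted, ]
  if (nrow(rec) == 0) {
    return(tibble::tibble(class = character(), offset_5p = integer(),
                          offset_3p = integer(), count = integer(),
                          fraction = double()))
  }
  rec |>
    dplyr::mutate(class = dplyr::case_when(
      .data$tail_class != "none" ~ .data$tail_class,
      .data$offset_5p == 0 & .data$offset_3p_templated == 0 &
        .data$internal_mismatches == 0 ~ "canonical",
      .data$internal_mismatches > 0 ~ "substitution",
      .default = "length_variant")) |>
    dplyr::group_by(.data$class,
                    offset_5p = dplyr::if_else(.data$class == "length_variant",
                                               .data$offset_5p, NA_integer_),
                    offset_3p = dplyr::if_else(.data$class == "length_variant",
                                               .data$offset_3p_templated,
                                               NA_integer_)) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::arrange(dplyr::desc(.data$count))
}

#' Detect alternative mature/mature* duplexes on a precursor
#'
#' Enumerates the observed read 5'-start positions on each arm (count
#' modes), builds a candidate mature interval per start (using the
#' most frequent read length at that start), and reports every arm
#' pairing whose duplex shows the canonical 2-nt 3' overhang on both
#' strands ([check_duplex_overhang()]). The canonical pair itself is
#' included and flagged, so overlapping alternative duplexes stand out
#' against it.
#'
#' @param members precursor alignments with `arm`, `prec_start`,
#'   `prec_end`, `count`.
#' @param fold the precursor [fold_mfe()] result.
#' @param canonical_5p,canonical_3p canonical arm intervals (precursor
#'   coordinates), used only for flagging.
#' @param min_count minimum summed count for a 5' start to be
#'   considered a mode (default 2).
#' @return tibble of duplexes: `start_5p`, `end_5p`, `start_3p`,
#'   `end_3p`, `count_5p`, `count_3p`, `overhang_5p`, `overhang_3p`,
#'   `canonical`.
#' @export
detect_alternative_duplex <- function(members, fold,
                                      canonical_5p = NULL,
                                      canonical_3p = NULL,
                                      min_count = 2) {
  modes <- function(arm) {
    m <- members[members$arm == arm, ]
    if (nrow(m) == 0) return(NULL)
    m |>
      dplyr::group_by(.data$prec_start) |>
      dplyr::summarise(
        count = sum(.data$count),
        len = .data$prec_end[which.max(.data$count)] -
          .data$prec_start[which.max(.data$count)],
        .groups = "drop") |>
      dplyr::filter(.data$count >= min_count)
  }
  m5 <- modes("5p"); m3 <- modes("3p")
  if (is.null(m5) || is.null(m3) || nrow(m5) == 0 || nrow(m3) == 0) {
    return(tibble::tibble())
  }
  grid <- tidyr::expand_grid(i = seq_len(nrow(m5)), j = seq_len(nrow(m3)))
  purrr::pmap(grid, function(i, j) {
    a5 <- c(m5$prec_start[i], m5$prec_start[i] + m5$len[i])
    a3 <- c(m3$prec_start[j], m3$prec_start[j] + m3$len[j])
    oh <- tryCatch(check_duplex_overhang(fold, a5, a3),
                   error = function(e) NULL)
    if (is.null(oh) || !oh$canonical) return(NULL)
    tibble::tibble(
      start_5p = a5[1], end_5p = a5[2], start_3p = a3[1], end_3p = a3[2],
      count_5p = m5$count[i], count_3p = m3$count[j],
      overhang_5p = oh$overhang_5p, overhang_3p = oh$overhang_3p,
      canonical = !is.null(canonical_5p) && !is.null(canonical_3p) &&
        all(a5 == canonical_5p) && all(a3 == canonical_3p))
  }) |> dplyr::bind_rows()
}
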