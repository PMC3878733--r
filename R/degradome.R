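# plant-style miRNA target scoring and degradome 5'-end cleavage calling

# pairing-state lookup: rows = miRNA base, cols = transcript base.
# G:U wobble on the RNA level is G:T / T:G in the DNA alphabet.
.BASES <- c("A", "C", "G", "T")
.PAIR_STATE <- local({
  m <- matrix("mismatch", 4, 4, dimnames = list(.BASES, .BASES))
  m["A", "T"] <- m["T", "A"] <- m["C", "G"] <- m["G", "C"] <- "match"
  m["G", "T"] <- m["T", "G"] <- "GU"
  m
})

# per-column pairing state of miRNA base vs transcript base (sense)
pair_state <- function(mir_base, t_base) {
  st <- .PAIR_STATE[cbind(match(mir_base, .BASES), match(t_base, .BASES))]
  st[is.na(st)] <- "mismatch"
  unname(st)
}

# penalty for one column; core (miRNA positions 2-13) doubles it
column_penalty <- function(state, mir_pos, mm = 1, gu = 0.5, gap = 2,
                           core = c(2, 13), core_mult = 2) {
  base <- unname(c(match = 0, GU = gu, mismatch = mm, gap = gap)[state])
  base[is.na(base)] <- mm              # non-ACGT columns score as mismatch
  mult <- ifelse(mir_pos >= core[1] & mir_pos <= core[2], core_mult, 1)
  base * mult
}

#' Score a miRNA against a transcript window
#'
#' Antiparallel complementarity scoring in the style of plant target
#' predictors: per-column penalties of 1 for a mismatch, 0.5 for a G:U
#' wobble and 2 for a gap, doubled inside the core (miRNA positions
#' 2-13 counted from the miRNA 5' end). The window may be one
#' nucleotide shorter or longer than the miRNA (at most one bulge on
#' either strand); every gap placement is tried and the best (lowest
#' penalty) alignment is returned.
#'
#' @param mirna miRNA sequence, 5' to 3'.
#' @param window transcript window, sense strand, 5' to 3'.
#' @param mm,gu,gap,core_mult penalty parameters.
#' @return a list with `penalty`, `states` (per-miRNA-position pairing
#'   state, 5' to 3'), and `gap_pos` (`NA`, or the miRNA position at /
#'   after which the single bulge sits).
#' @export
score_target_alignment <- function(mirna, window, mm = 1, gu = 0.5,
                                   gap = 2, core_mult = 2) {
  n <- nchar(mirna)
  wlen <- nchar(window)
  if (abs(wlen - n) > 1) {
    abort("window length must be within one nt of the miRNA length")
  }
  mir <- strsplit(mirna, "")[[1]]
  # reverse (not complement): wrev[i] faces miRNA position i
  wrev <- rev(strsplit(window, "")[[1]])

  score_gapless <- function(mvec, wvec, mpos) {
    st <- pair_state(mvec, wvec)
    list(penalty = sum(column_penalty(st, mpos, mm, gu, gap,
                                      core_mult = core_mult)),
         states = st)
  }
  if (wlen == n) {
    res <- score_gapless(mir, wrev, seq_len(n))
    return(list(penalty = res$penalty, states = res$states,
                gap_pos = NA_integer_))
  }
  best <- NULL
  if (wlen == n - 1) {
    # one miRNA base bulged (gap in the transcript) at position g
    for (g in seq_len(n)) {
      mvec <- mir[-g]
      res <- score_gapless(mvec, wrev, seq_len(n)[-g])
      pen <- res$penalty + column_penalty("gap", g, mm, gu, gap,
                                          core_mult = core_mult)
      if (is.null(best) || pen < best$penalty) {
        st <- character(n); st[g] <- "gap"; st[-g] <- res$states
        best <- list(penalty = pen, states = st, gap_pos = g)
      }
    }
  } else {
    # one transcript base bulged (gap in the miRNA) after position g
    for (g in 0:n) {
      keep <- setdiff(seq_len(wlen), g + 1)
      res <- score_gapless(mir, wrev[keep], seq_len(n))
      pen <- res$penalty + column_penalty("gap", max(g, 1), mm, gu, gap,
                                          core_mult = core_mult)
      if (is.null(best) || pen < best$penalty) {
        best <- list(penalty = pen, states = res$states, gap_pos = g)
      }
    }
  }
  best
}

#' Predict miRNA target sites on transcripts
#'
#' Scores every window (miRNA length and plus/minus one nt) of every
#' transcript with [score_target_alignment()] and keeps sites whose
#' penalty is at most `max_penalty`. Overlapping windows for the same
#' miRNA/transcript collapse to the best-scoring one, so each site is
#' reported once; distinct sites on one transcript are reported
#' separately.
#'
#' @param mirna named list or single sequence; use [predict_targets_set()]
#'   for several miRNAs.
#' @param transcripts tibble (`name`, `seq`).
#' @param max_penalty score cutoff (default 3).
#' @param mirna_id label for the output (default `"mirna"`).
#' @return tibble of sites: `mirna_id`, `transcript`, `start`, `end`
#'   (0-based half-open window on the transcript), `penalty`,
#'   `gap_pos`, `n_mismatch`, `n_gu`.
#' @export
predict_targets <- function(mirna, transcripts, max_penalty = 3,
                            mirna_id = "mirna") {
  n <- nchar(mirna)
  hits <- purrr::map2(transcripts$name, transcripts$seq, function(nm, tx) {
    cand <- scan_target_windows(mirna, tx, max_penalty)
    if (nrow(cand) == 0) return(cand)
    # detail columns from the reference scorer (same model, per window)
    det <- purrr::pmap(cand, function(start, end, penalty) {
      res <- score_target_alignment(mirna, substr(tx, start + 1, end))
      tibble::tibble(penalty = res$penalty,
                     gap_pos = res$gap_pos %||% NA_integer_,
                     n_mismatch = sum(res$states == "mismatch"),
                     n_gu = sum(res$states == "GU"))
    }) |> dplyr::bind_rows()
    tibble::tibble(mirna_id = mirna_id, transcript = nm,
                   start = cand$start, end = cand$end,
                   penalty = det$penalty, gap_pos = det$gap_pos,
                   n_mismatch = det$n_mismatch, n_gu = det$n_gu)
  }) |> dplyr::bind_rows()
  if (nrow(hits) == 0) return(hits)
  # collapse overlapping windows to the local optimum
  hits |>
    dplyr::group_by(.data$transcript) |>
    dplyr::arrange(.data$penalty, .data$start, .data$end - .data$start,
                   .by_group = TRUE) |>
    dplyr::group_modify(function(d, g) {
      keep <- rep(TRUE, nrow(d))
      for (i in seq_len(nrow(d))) {
        if (!keep[i]) next
        later <- which(keep & seq_len(nrow(d)) > i)
        ov <- d$start[later] < d$end[i] & d$start[i] < d$end[later]
        keep[later[ov]] <- FALSE
      }
      d[keep, ]
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$transcript, .data$start)
}

# vectorised window scan: for every start and window length n-1/n/n+1,
# the minimum penalty over gap placements, via shifted lookups into a
# per-position penalty matrix. Same model as score_target_alignment().
scan_target_windows <- function(mirna, tx, max_penalty) {
  n <- nchar(mirna)
  tlen <- nchar(tx)
  empty <- tibble::tibble(start = integer(), end = integer(),
                          penalty = double())
  if (tlen < n - 1) return(empty)
  mc <- match(strsplit(mirna, "")[[1]], .BASES)
  tc <- match(strsplit(tx, "")[[1]], .BASES)
  tc[is.na(tc)] <- 5L
  # per-column penalties including the core multiplier
  pen4 <- matrix(1, 4, 5)                      # mismatch default
  pen4[cbind(c(1, 4, 2, 3), c(4, 1, 3, 2))] <- 0      # WC match
  pen4[3, 4] <- pen4[4, 3] <- 0.5                     # G:U
  mult <- ifelse(seq_len(n) >= 2 & seq_len(n) <= 13, 2, 1)
  PM <- matrix(0, n, tlen)
  for (p in seq_len(n)) PM[p, ] <- pen4[mc[p], tc] * mult[p]
  gp <- function(g) 2 * ifelse(g >= 2 & g <= 13, 2, 1)

  shift_row <- function(p, off, len) {
    # PM[p, s0 + off] for s0 = 0..len-1 (1-based transcript index off..)
    PM[p, off:(off + len - 1)]
  }
  out <- list()
  # gapless
  if (tlen >= n) {
    len <- tlen - n + 1
    pen <- Reduce(`+`, lapply(seq_len(n), function(p)
      shift_row(p, n - p + 1, len)))
    keep <- which(pen <= max_penalty)
    if (length(keep) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        start = keep - 1L, end = keep - 1L + n, penalty = pen[keep])
    }
  }
  # window one shorter: one miRNA base bulged at g
  if (tlen >= n - 1) {
    len <- tlen - (n - 1) + 1
    A <- lapply(seq_len(n), function(p) shift_row(p, max(n - p, 1), len) *
                  as.numeric(n - p >= 1))
    A[[n]] <- rep(0, len)                       # p = n never in prefix
    B <- lapply(seq_len(n), function(p) {
      if (p == 1) rep(0, len)                   # p = 1 never in suffix
      else shift_row(p, n - p + 1, len)
    })
    prefA <- Reduce(`+`, A, accumulate = TRUE)  # prefA[[k]] = sum p<=k
    sufB <- rev(Reduce(`+`, rev(B), accumulate = TRUE)) # sufB[[k]] = sum p>=k
    best <- NULL
    for (g in seq_len(n)) {
      pen <- gp(g) +
        (if (g > 1) prefA[[g - 1]] else 0) +
        (if (g < n) sufB[[g + 1]] else 0)
      best <- if (is.null(best)) pen else pmin(best, pen)
    }
    keep <- which(best <= max_penalty)
    if (length(keep) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        start = keep - 1L, end = keep - 1L + n - 1L, penalty = best[keep])
    }
  }
  # window one longer: one transcript base bulged after g
  if (tlen >= n + 1) {
    len <- tlen - (n + 1) + 1
    C <- lapply(seq_len(n), function(p) shift_row(p, n - p + 2, len))
    B <- lapply(seq_len(n), function(p) shift_row(p, n - p + 1, len))
    prefC <- Reduce(`+`, C, accumulate = TRUE)
    sufB <- rev(Reduce(`+`, rev(B), accumulate = TRUE))
    best <- NULL
    for (g in 0:n) {
      pen <- gp(max(g, 1)) +
        (if (g >= 1) prefC[[g]] else 0) +
        (if (g < n) sufB[[g + 1]] else 0)
      best <- if (is.null(best)) pen else pmin(best, pen)
    }
    keep <- which(best <= max_penalty)
    if (length(keep) > 0) {
      out[[length(out) + 1]] <- tibble::tibble(
        start = keep - 1L, end = keep - 1L + n + 1L, penalty = best[keep])
    }
  }
  if (length(out) == 0) empty else dplyr::bind_rows(out)
}

#' Predict targets for a set of miRNAs
#'
#' @param mirnas tibble (`name`, `seq`).
#' @inheritParams predict_targets
#' @return row-bound [predict_targets()] tables.
#' @export
predict_targets_set <- function(mirnas, transcripts, max_penalty = 3) {
  purrr::map2(mirnas$name, mirnas$seq, function(nm, sq) {
    predict_targets(sq, transcripts, max_penalty = max_penalty,
                    mirna_id = nm)
  }) |> dplyr::bind_rows()
}

#' Pile up degradome tags over a target site and call cleavage
#'
#' Degradome tags are 5'-ends of uncapped transcript fragments; each
#' tag is anchored to the transcript by an exact prefix match of
#' `anchor_len` nt (the MmeI tag length). Within the site the modal 5'
#' position is reported, converted to a position relative to the miRNA
#' 5' end under the convention that transcript base `t` inside a
#' gapless site `[s, s + m)` pairs miRNA position `s + m - t` - so a
#' canonical slice between the bases paired with miRNA positions 10
#' and 11 places the fragment 5'-end at relative position 10. Calls at
#' relative positions 10 or 11 are `canonical_10_11`; everything else
#' is `other`. A call whose modal count is compatible with a uniform
#' background across the site (one-sided binomial tail, Bonferroni
#' corrected across site positions, p >= 0.05) is flagged low
#' confidence.
#'
#' @param site one row of a [predict_targets()] table.
#' @param tags degradome tags tibble (`read_id`, `seq`, `count`).
#' @param transcript the transcript sequence the site lives on.
#' @param anchor_len exact-prefix anchor length (default 20).
#' @return a one-row tibble (`cleavage_pos`, `relative_pos`,
#'   `category`, `supporting_count`, `site_total`, `low_confidence`)
#'   or `NULL` when no tag falls inside the site.
#' @export
pileup_and_call <- function(site, tags, transcript, anchor_len = 20) {
  pos5 <- purrr::map_int(tags$seq, function(sq) {
    p <- regexpr(substr(sq, 1, anchor_len), transcript, fixed = TRUE)[1]
    if (p < 0) NA_integer_ else as.integer(p - 1L)   # 0-based
  })
  keep <- !is.na(pos5) & pos5 >= site$start & pos5 < site$end
  if (!any(keep)) return(NULL)
  pile <- tibble::tibble(pos = pos5[keep], count = tags$count[keep]) |>
    dplyr::group_by(.data$pos) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  modal <- pile[which.max(pile$count), ]
  m <- site$end - site$start
  relative <- site$end - modal$pos
  total <- sum(pile$count)
  # uniform-background check on the modal count
  p_uniform <- pbinom(modal$count - 1, total, 1 / m, lower.tail = FALSE) * m
  tibble::tibble(
    mirna_id = site$mirna_id, transcript = site$transcript,
    site_start = site$start, site_end = site$end,
    cleavage_pos = modal$pos,
    relative_pos = as.integer(relative),
    category = dplyr::if_else(relative %in% c(10, 11),
                              "canonical_10_11", "other"),
    supporting_count = modal$count, site_total = total,
    low_confidence = p_uniform >= 0.05)
}

#' Call cleavage over all predicted sites
#'
#' @param sites a [predict_targets_set()] table.
#' @param tags degradome tags tibble.
#' @param transcripts transcript tibble (`name`, `seq`).
#' @inheritParams pileup_and_call
#' @return tibble of cleavage calls, one row per site with tag support.
#' @export
call_cleavage <- function(sites, tags, transcripts, anchor_len = 20) {
  purrr::map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    tx <- transcripts$seq[transcripts$name == s$transcript]
    pileup_and_call(s, tags, tx, anchor_len = anchor_len)
  }) |> dplyr::bind_rows()
}
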