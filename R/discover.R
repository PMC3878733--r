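# locus discovery: precursor extraction, filter cascade, homology expansion

# genomic interval -> precursor coordinates (0-based half-open both ways)
to_prec <- function(gstart, gend, span_start, span_end, strand) {
  if (strand == "+") c(gstart - span_start, gend - span_start)
  else c(span_end - gend, span_end - gstart)
}

#' Extract a precursor candidate from a cluster pair
#'
#' Pulls the genomic sequence spanned by the two clusters (reverse
#' complemented on the minus strand so the candidate reads 5' to 3'),
#' carrying the member alignments of both clusters in precursor
#' coordinates. The 5p arm is the cluster nearer the candidate's 5'
#' end: the upstream cluster on the plus strand, the downstream one on
#' the minus strand.
#'
#' @param pair one row of a [pair_clusters()] tibble.
#' @param clusters the [cluster_reads()] tibble the pair refers to.
#' @param genome genome tibble (`name`, `seq`).
#' @param flank extra genomic context added on both sides (default 0).
#' @return a `precursor_candidate` list: `chrom`, `strand`, `start`,
#'   `end`, `seq`, `arm_5p`, `arm_3p` (precursor-coordinate intervals),
#'   `members` (alignments annotated with `prec_start`, `prec_end`,
#'   `arm`), `fold` (unset), `verdict` (unset).
#' @export
extract_precursor <- function(pair, clusters, genome, flank = 0) {
  ca <- clusters[clusters$cluster_id == pair$cluster_a, ]
  cb <- clusters[clusters$cluster_id == pair$cluster_b, ]
  gseq <- genome$seq[genome$name == pair$chrom]
  if (length(gseq) != 1) abort(paste0("chromosome not in genome: ", pair$chrom))
  span_start <- min(ca$start, cb$start) - flank
  span_end <- max(ca$end, cb$end) + flank
  if (span_start < 0 || span_end > nchar(gseq)) {
    abort("precursor span exceeds chromosome bounds")
  }
  seq <- substr(gseq, span_start + 1, span_end)
  strand <- pair$strand
  if (strand == "-") seq <- revcomp(seq)
  arm_a <- to_prec(ca$start, ca$end, span_start, span_end, strand)
  arm_b <- to_prec(cb$start, cb$end, span_start, span_end, strand)
  up_is_5p <- strand == "+"
  members <- dplyr::bind_rows(
    dplyr::mutate(ca$members[[1]], arm = if (up_is_5p) "5p" else "3p"),
    dplyr::mutate(cb$members[[1]], arm = if (up_is_5p) "3p" else "5p"))
  prec <- t(mapply(to_prec, members$start, members$end,
                   MoreArgs = list(span_start = span_start,
                                   span_end = span_end, strand = strand)))
  members$prec_start <- prec[, 1]
  members$prec_end <- prec[, 2]
  structure(list(
    chrom = pair$chrom, strand = strand,
    start = span_start, end = span_end, seq = seq,
    cluster_a = pair$cluster_a, cluster_b = pair$cluster_b,
    arm_5p = if (up_is_5p) arm_a else arm_b,
    arm_3p = if (up_is_5p) arm_b else arm_a,
    members = members, fold = NULL, verdict = NULL
  ), class = "precursor_candidate")
}

#' @export
print.precursor_candidate <- function(x, ...) {
  cat(sprintf("<precursor_candidate> %s:%d-%d(%s), %d nt, %d member reads\n",
              x$chrom, x$start, x$end, x$strand, nchar(x$seq),
              nrow(x$members)))
  if (!is.null(x$fold)) cat(sprintf("  mfe %.2f kcal/mol\n", x$fold$mfe))
  if (!is.null(x$verdict)) {
    cat(sprintf("  %s%s\n", if (x$verdict$accepted) "ACCEPTED" else "rejected",
                if (length(x$verdict$reasons) > 0)
                  paste0(" [", paste(x$verdict$reasons, collapse = ","), "]")
                else ""))
  }
  invisible(x)
}

# count-weighted fraction of members sharing the modal 5' start, per arm
modal_5p_fraction <- function(members) {
  members |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      frac = max(tapply(.data$count, .data$prec_start, sum)) /
        sum(.data$count), .groups = "drop")
}

#' Apply the acceptance filters to a folded precursor candidate
#'
#' Four filters, each contributing a reason code on failure:
#' * `MFE` - minimum free energy at most `mfe_max` (default -35
#'   kcal/mol);
#' * `STEM` - count-weighted fraction of arm reads lying fully within
#'   the paired stem regions at least `stem_min` (default 0.9); a
#'   multi-branched or unfolded structure fails outright;
#' * `FIVE_PRIME` - on each arm, the count-weighted fraction of reads
#'   sharing the modal 5' start position at least `homog_min`
#'   (default 0.5), formalising "little fluctuation around the 5'
#'   start";
#' * `FAMILY` - the dominant 3p-arm read matches the reference mature
#'   set within `max_mm` mismatches (skipped when `mode = "denovo"`).
#'
#' @param candidate a folded `precursor_candidate`.
#' @param family_refs reference mature set (`name`, `seq` tibble);
#'   required in family mode.
#' @param mfe_max,stem_min,homog_min,max_mm filter thresholds.
#' @param stem_slack nt by which the stem intervals are expanded before
#'   the containment test, matching the isomiR window (default 5).
#' @param mode `"family"` applies the reference-match filter,
#'   `"denovo"` skips it.
#' @return the candidate with `verdict` set: a list with `accepted`,
#'   `reasons` (character vector of failed-filter codes), and the
#'   measured `mfe`, `stem_fraction`, `five_prime_fraction`, `family`.
#' @export
validate_candidate <- function(candidate, family_refs = NULL,
                               mfe_max = -35, stem_min = 0.9,
                               homog_min = 0.5, max_mm = 2, stem_slack = 5,
                               mode = c("family", "denovo")) {
  mode <- match.arg(mode)
  if (is.null(candidate$fold)) {
    abort("candidate must be folded before validation")
  }
  reasons <- character(0)
  if (candidate$fold$mfe > mfe_max) reasons <- c(reasons, "MFE")

  anat <- annotate_hairpin(candidate$fold)
  m <- candidate$members
  stem_frac <- 0
  if (anat$multiloop || anat$unfolded) {
    reasons <- c(reasons, "STEM")
  } else {
    # stems expanded by the isomiR window flank: a Dicer product carries
    # up to stem_slack nt of templated 3' variation past the paired
    # region, which must not count against the stem filter
    on_stem <-
      (m$prec_start >= anat$stem5p[1] - stem_slack &
         m$prec_end <= anat$stem5p[2] + stem_slack) |
      (m$prec_start >= anat$stem3p[1] - stem_slack &
         m$prec_end <= anat$stem3p[2] + stem_slack)
    stem_frac <- sum(m$count[on_stem]) / sum(m$count)
    if (stem_frac < stem_min) reasons <- c(reasons, "STEM")
  }

  fp <- modal_5p_fraction(m)
  if (min(fp$frac) < homog_min) reasons <- c(reasons, "FIVE_PRIME")

  family <- NA_character_
  if (mode == "family") {
    if (is.null(family_refs) || nrow(family_refs) == 0) {
      abort("family mode requires a non-empty reference mature set")
    }
    m3 <- m[m$arm == "3p", ]
    dom <- m3$seq[which.max(m3$count)]
    hits <- match_reference_set(dom, family_refs, max_mm = max_mm)
    if (nrow(hits) == 0) reasons <- c(reasons, "FAMILY")
    else family <- hits$reference_id[hits$best][1]
  }

  candidate$verdict <- list(
    accepted = length(reasons) == 0,
    reasons = reasons, mfe = candidate$fold$mfe,
    stem_fraction = stem_frac,
    five_prime_fraction = min(fp$frac),
    family = family)
  candidate
}

# dominant read of one arm: seq + genomic interval
dominant_arm_read <- function(members, arm) {
  m <- members[members$arm == arm, ]
  if (nrow(m) == 0) return(NULL)
  m[which.max(m$count), ]
}

#' Discover miRNA loci from collapsed reads and a genome
#'
#' The full discovery cascade: exact genome mapping, greedy
#' count-ordered clustering, pairing of clusters separated by less than
#' `max_gap` nt, precursor extraction and folding, filter validation
#' ([validate_candidate()]), then homology expansion of each accepted
#' mature sequence across the genome ([homology_expand()]). Loci that
#' share an identical mature 3p sequence receive one name with a
#' numeric identifier suffix.
#'
#' @param reads collapsed reads tibble (`read_id`, `seq`, `count`).
#' @param genome genome tibble (`name`, `seq`).
#' @param mature_refs reference mature set; required unless
#'   `mode = "denovo"`.
#' @param mode,max_mm,max_gap,mfe_max,stem_min,homog_min see
#'   [validate_candidate()] and [pair_clusters()].
#' @param flank genomic flank added to extracted precursors (default 0).
#' @param homology_window half-width of the window refolded around each
#'   genomic copy of a mature sequence (default 120 nt, generous for
#'   plant pre-miRNAs).
#' @param engine folding engine (`NULL` = built-in).
#' @param k k-mer size for the genome index.
#' @return a `mirna_discovery` object; `tidy()` it for the locus table,
#'   `glance()` for a one-row run summary. Components: `loci` (accepted
#'   locus tibble), `candidates` (every evaluated cluster pair with its
#'   verdict), `clusters`, `pairs`, `alignments`, `params`.
#' @export
discover_loci <- function(reads, genome, mature_refs = NULL,
                          mode = c("family", "denovo"), max_mm = 2,
                          max_gap = 150, mfe_max = -35, stem_min = 0.9,
                          homog_min = 0.5, flank = 0,
                          homology_window = 120, engine = NULL, k = 12) {
  mode <- match.arg(mode)
  index <- build_kmer_index(genome, k = k)
  alignments <- map_reads(reads, index)
  clusters <- cluster_reads(alignments)
  pairs <- pair_clusters(clusters, max_gap = max_gap)

  cands <- purrr::map(seq_len(nrow(pairs)), function(i) {
    cand <- extract_precursor(pairs[i, ], clusters, genome, flank = flank)
    cand$fold <- fold_mfe(cand$seq, engine = engine)
    validate_candidate(cand, family_refs = mature_refs, mfe_max = mfe_max,
                       stem_min = stem_min, homog_min = homog_min,
                       max_mm = max_mm, mode = mode)
  })

  cand_tbl <- tibble::tibble(
    cluster_a = pairs$cluster_a, cluster_b = pairs$cluster_b,
    chrom = pairs$chrom, strand = pairs$strand,
    start = purrr::map_int(cands, ~ as.integer(.x$start)),
    end = purrr::map_int(cands, ~ as.integer(.x$end)),
    mfe = purrr::map_dbl(cands, ~ .x$verdict$mfe),
    stem_fraction = purrr::map_dbl(cands, ~ .x$verdict$stem_fraction),
    five_prime_fraction = purrr::map_dbl(cands,
                                         ~ .x$verdict$five_prime_fraction),
    total_count = purrr::map_int(cands, ~ sum(.x$members$count)),
    accepted = purrr::map_lgl(cands, ~ .x$verdict$accepted),
    reasons = purrr::map_chr(cands,
                             ~ paste(.x$verdict$reasons, collapse = ",")),
    family = purrr::map_chr(cands, ~ .x$verdict$family %||% NA_character_),
    candidate = cands)

  # de-novo loci from accepted candidates; overlapping accepted
  # candidates (either strand - the reverse complement of a hairpin is
  # itself a hairpin, so antisense reads can nominate a mirror locus)
  # collapse to the one carrying the read majority, then lowest mfe
  acc <- cand_tbl[cand_tbl$accepted, ]
  if (nrow(acc) > 0) {
    acc <- acc |>
      dplyr::arrange(dplyr::desc(.data$total_count), .data$mfe) |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(function(d, g) {
        keep <- rep(TRUE, nrow(d))
        for (i in seq_len(nrow(d))) {
          if (!keep[i]) next
          for (j in seq_len(nrow(d))) {
            if (j <= i || !keep[j]) next
            if (d$start[j] < d$end[i] && d$start[i] < d$end[j]) keep[j] <- FALSE
          }
        }
        d[keep, ]
      }) |>
      dplyr::ungroup()
  }

  loci <- purrr::map(seq_len(nrow(acc)), function(i) {
    locus_from_candidate(acc$candidate[[i]], source = "de_novo")
  }) |> dplyr::bind_rows()

  if (nrow(loci) > 0) {
    expanded <- purrr::map(unique(loci$mature_3p_seq), function(mat) {
      homology_expand(mat, genome, index = index, existing = loci,
                      mfe_max = mfe_max, window = homology_window,
                      engine = engine)
    }) |> dplyr::bind_rows()
    loci <- dplyr::bind_rows(loci, expanded)
    loci <- name_loci(loci)
  }

  structure(list(
    loci = loci, candidates = cand_tbl, clusters = clusters, pairs = pairs,
    alignments = alignments,
    params = list(mode = mode, max_mm = max_mm, max_gap = max_gap,
                  mfe_max = mfe_max, stem_min = stem_min,
                  homog_min = homog_min, flank = flank,
                  homology_window = homology_window, k = k),
    stats = list(n_reads = nrow(reads),
                 n_read_count = sum(reads$count),
                 n_mapped = length(unique(alignments$read_id)),
                 n_clusters = nrow(clusters), n_pairs = nrow(pairs),
                 n_accepted = sum(cand_tbl$accepted))
  ), class = "mirna_discovery")
}

# build one locus row from an accepted candidate
locus_from_candidate <- function(cand, source) {
  d5 <- dominant_arm_read(cand$members, "5p")
  d3 <- dominant_arm_read(cand$members, "3p")
  fam <- cand$verdict$family %||% NA_character_
  tibble::tibble(
    locus_id = NA_character_,
    family = fam %||% NA_character_,
    source = source,
    chrom = cand$chrom, strand = cand$strand,
    start = as.integer(cand$start), end = as.integer(cand$end),
    mfe = cand$fold$mfe, structure = cand$fold$structure, seq = cand$seq,
    mature_5p_seq = d5$seq %||% NA_character_,
    mature_3p_seq = d3$seq %||% NA_character_,
    mature_5p_start = as.integer(d5$start %||% NA),
    mature_5p_end = as.integer(d5$end %||% NA),
    mature_3p_start = as.integer(d3$start %||% NA),
    mature_3p_end = as.integer(d3$end %||% NA))
}

# one name per distinct mature 3p sequence, numeric suffix per gene copy
name_loci <- function(loci) {
  loci |>
    dplyr::group_by(.data$mature_3p_seq) |>
    dplyr::mutate(.fam = dplyr::first(stats::na.omit(.data$family)) %||%
                    NA_character_) |>
    dplyr::ungroup() |>
    dplyr::mutate(.key = dplyr::if_else(
      is.na(.data$.fam),
      paste0("novel-", dplyr::dense_rank(.data$mature_3p_seq)),
      .data$.fam)) |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(.data$chrom, .data$start, .by_group = TRUE) |>
    dplyr::mutate(locus_id = if (dplyr::n() == 1) paste0("MIR-", .data$.key)
                  else paste0("MIR-", .data$.key, "-", dplyr::row_number()),
                  family = .data$.key) |>
    dplyr::ungroup() |>
    dplyr::select(-".fam", -".key") |>
    dplyr::arrange(.data$chrom, .data$start)
}

#' Expand an accepted mature sequence across the genome
#'
#' Maps a mature miRNA exactly to the genome and, for every placement
#' outside already-known loci, extracts a window of `window` nt on
#' either side and folds it; the putative precursor is then trimmed to
#' the stem-loop spanning the mature and the arm it pairs with
#' (flanking sequence is context, not precursor), refolded, and the
#' placement is accepted as an additional gene when that hairpin
#' reaches `mfe_max` and the mature sequence lies on one of its stems.
#' This recovers all genes giving rise to the same mature miRNA.
#'
#' @param mature mature sequence (guide strand) from an accepted locus.
#' @param genome genome tibble.
#' @param index optional prebuilt [build_kmer_index()]; built on the
#'   fly when `NULL`.
#' @param existing locus tibble to avoid re-reporting (may be `NULL`).
#' @param mfe_max acceptance threshold (default -35 kcal/mol).
#' @param window half-width of the refolded window (default 120 nt).
#' @param engine folding engine.
#' @return a locus tibble (possibly empty) with `source =
#'   "homology_expanded"`.
#' @export
homology_expand <- function(mature, genome, index = NULL, existing = NULL,
                            mfe_max = -35, window = 120, engine = NULL) {
  index <- index %||% build_kmer_index(genome)
  hits <- map_read_exact(mature, index)
  out <- purrr::map(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (!is.null(existing) && nrow(existing) > 0) {
      ov <- existing$chrom == h$chrom & existing$strand == h$strand &
        existing$start < h$end & h$start < existing$end
      if (any(ov)) return(NULL)
    }
    gseq <- genome$seq[genome$name == h$chrom]
    ws <- max(0, h$start - window)
    we <- min(nchar(gseq), h$end + window)
    wseq <- substr(gseq, ws + 1, we)
    if (h$strand == "-") wseq <- revcomp(wseq)
    wfold <- fold_mfe(wseq, engine = engine)
    # locate the putative precursor inside the window: the mature plus
    # the arm it pairs with; flanking sequence outside that stem-loop
    # is context, not precursor
    mat_w <- to_prec(h$start, h$end, ws, we, h$strand)
    partner <- pair_table(wfold$structure)
    mate <- partner[(mat_w[1] + 1):mat_w[2]]
    mate <- mate[!is.na(mate)]
    if (length(mate) < 10) return(NULL)       # mature barely paired
    ps <- min(mat_w[1], min(mate))
    pe <- max(mat_w[2], max(mate) + 1L)
    seq <- substr(wseq, ps + 1, pe)
    fold <- fold_mfe(seq, engine = engine)
    if (fold$mfe > mfe_max) return(NULL)
    anat <- annotate_hairpin(fold)
    if (anat$multiloop || anat$unfolded) return(NULL)
    mat <- mat_w - ps
    slack <- 5
    on_stem <- (mat[1] >= anat$stem5p[1] - slack &&
                  mat[2] <= anat$stem5p[2] + slack) ||
      (mat[1] >= anat$stem3p[1] - slack && mat[2] <= anat$stem3p[2] + slack)
    if (!on_stem) return(NULL)
    mature_is_5p <- mat[2] <= anat$loop[1]
    # genomic span of the trimmed precursor
    if (h$strand == "+") {
      ws <- ws + ps
      we <- ws + (pe - ps)
    } else {
      we2 <- we - ps
      ws <- we2 - (pe - ps)
      we <- we2
    }
    tibble::tibble(
      locus_id = NA_character_, family = NA_character_,
      source = "homology_expanded",
      chrom = h$chrom, strand = h$strand,
      start = as.integer(ws), end = as.integer(we),
      mfe = fold$mfe, structure = fold$structure, seq = seq,
      mature_5p_seq = if (mature_is_5p) mature else NA_character_,
      mature_3p_seq = if (mature_is_5p) NA_character_ else mature,
      mature_5p_start = as.integer(if (mature_is_5p) h$start else NA),
      mature_5p_end = as.integer(if (mature_is_5p) h$end else NA),
      mature_3p_start = as.integer(if (mature_is_5p) NA else h$start),
      mature_3p_end = as.integer(if (mature_is_5p) NA else h$end))
  })
  dplyr::bind_rows(out)
}

#' @export
print.mirna_discovery <- function(x, ...) {
  cat(sprintf(paste0("<mirna_discovery> %d reads (%d sequenced), ",
                     "%d clusters, %d pairs, %d loci accepted\n"),
              x$stats$n_reads, x$stats$n_read_count, x$stats$n_clusters,
              x$stats$n_pairs, nrow(x$loci)))
  invisible(x)
}
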