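#' Build a k-mer index over a genome
#'
#' Indexes every overlapping k-mer of the plus strand of each sequence.
#' The minus strand is handled at query time by reverse-complementing
#' the read, so the index itself stores each position exactly once.
#'
#' @param genome a tibble with columns `name`, `seq` (as from
#'   [load_fasta()]).
#' @param k k-mer size; must be at least 8 and no longer than the
#'   shortest read you intend to map (default 12).
#' @return a `kmer_index` object.
#' @export
build_kmer_index <- function(genome, k = 12) {
  if (k < 8) abort("k-mer size below 8 is not supported (too unspecific)")
  per_chrom <- purrr::map2(genome$name, genome$seq, function(nm, sq) {
    n <- nchar(sq)
    if (n < k) return(NULL)
    pos <- 0:(n - k)                                   # 0-based
    tibble::tibble(kmer = substring(sq, pos + 1, pos + k),
                   chrom = nm, pos = pos)
  })
  tab <- dplyr::bind_rows(per_chrom)
  idx <- split(seq_len(nrow(tab)), tab$kmer)
  structure(list(k = k, table = tab, lookup = idx,
                 genome = setNames(genome$seq, genome$name)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf("<kmer_index> k=%d, %d sequences, %d indexed positions\n",
              x$k, length(x$genome), nrow(x$table)))
  invisible(x)
}

# all perfect full-length placements of one sequence on one strand
exact_hits_one_strand <- function(seq, index, strand) {
  query <- if (strand == "+") seq else revcomp(seq)
  len <- nchar(query)
  rows <- index$lookup[[substr(query, 1, index$k)]]
  if (is.null(rows)) return(NULL)
  cand <- index$table[rows, ]
  gseq <- index$genome[cand$chrom]
  glen <- nchar(gseq)
  ok <- cand$pos + len <= glen &
    substring(gseq, cand$pos + 1, cand$pos + len) == query
  if (!any(ok)) return(NULL)
  tibble::tibble(chrom = cand$chrom[ok], start = cand$pos[ok],
                 end = cand$pos[ok] + len, strand = strand)
}

#' Map a read to the genome, exact matches only
#'
#' Returns every perfect full-length placement on both strands. Genome
#' mapping in this pipeline is exact by design: mismatch tolerance is
#' reserved for matching against reference mature sets
#' ([match_reference_set()]).
#'
#' @param seq a single read sequence.
#' @param index a [build_kmer_index()] object.
#' @return a tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, sorted by (`chrom`, `start`, `strand`); zero
#'   rows when the read does not map. A minus-strand row means the
#'   reverse complement of the read equals the genome slice.
#' @export
map_read_exact <- function(seq, index) {
  if (nchar(seq) < index$k) abort("read shorter than the k-mer size")
  hits <- dplyr::bind_rows(exact_hits_one_strand(seq, index, "+"),
                           exact_hits_one_strand(seq, index, "-"))
  if (nrow(hits) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  dplyr::arrange(hits, .data$chrom, .data$start, .data$strand)
}

#' Map a table of collapsed reads to the genome
#'
#' Exact mapping of every read; multi-mapping reads contribute one row
#' per placement and are counted fully at every placement. `n_hits`
#' annotates how many placements each read has (1 = mapped uniquely).
#'
#' @param reads a tibble with columns `read_id`, `seq`, `count`.
#' @param index a [build_kmer_index()] object.
#' @return a tibble of alignments: `read_id`, `seq`, `count`, `chrom`,
#'   `start`, `end`, `strand`, `n_hits`.
#' @export
map_reads <- function(reads, index) {
  hits <- purrr::map(reads$seq, map_read_exact, index = index)
  n <- purrr::map_int(hits, nrow)
  aln <- dplyr::bind_cols(
    reads[rep(seq_len(nrow(reads)), n), ],
    dplyr::bind_rows(hits)
  )
  aln |>
    dplyr::mutate(n_hits = rep(n[n > 0], n[n > 0])) |>
    dplyr::arrange(.data$chrom, .data$start, .data$strand)
}

#' Match a read against a reference mature-miRNA set
#'
#' Slides the read along each reference without gaps and reports every
#' offset whose overlap is at least `min_overlap` nucleotides with at
#' most `max_mm` mismatches inside the overlap. This models alignment
#' of sequencing reads to a miRBase-style mature set with 0--2
#' mismatches allowed.
#'
#' @param seq a single read sequence.
#' @param references tibble with columns `name`, `seq` (the mature set).
#' @param max_mm maximum Hamming mismatches within the overlap (0--2).
#' @param min_overlap minimum ungapped overlap in nt (default 16).
#' @return tibble with columns `reference_id`, `offset` (read 5' minus
#'   reference 5'), `overlap`, `mismatches`, and `best` (`TRUE` on the
#'   fewest-mismatch match, ties broken towards longer overlap then
#'   smaller absolute offset).
#' @export
match_reference_set <- function(seq, references, max_mm = 2,
                                min_overlap = 16) {
  if (!max_mm %in% 0:2) abort("max_mm must be 0, 1 or 2")
  if (nrow(references) == 0) abort("reference set is empty")
  rl <- nchar(seq)
  rcs <- strsplit(seq, "")[[1]]
  res <- purrr::map2(references$name, references$seq, function(nm, ref) {
    refl <- nchar(ref)
    refc <- strsplit(ref, "")[[1]]
    offs <- (-(rl - min_overlap)):(refl - min_overlap)
    purrr::map(offs, function(o) {
      i0 <- max(0L, o); i1 <- min(refl, o + rl)   # overlap on reference
      ov <- i1 - i0
      if (ov < min_overlap) return(NULL)
      mm <- sum(refc[(i0 + 1):i1] != rcs[(i0 - o + 1):(i1 - o)])
      if (mm > max_mm) return(NULL)
      tibble::tibble(reference_id = nm, offset = o,
                     overlap = ov, mismatches = mm)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(res) == 0) {
    return(tibble::tibble(reference_id = character(), offset = integer(),
                          overlap = integer(), mismatches = integer(),
                          best = logical()))
  }
  best <- res |>
    dplyr::arrange(.data$mismatches, dplyr::desc(.data$overlap),
                   abs(.data$offset)) |>
    dplyr::slice(1)
  res |>
    dplyr::mutate(best = .data$reference_id == best$reference_id &
                    .data$offset == best$offset &
                    .data$mismatches == best$mismatches) |>
    dplyr::arrange(.data$reference_id, .data$offset)
}
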