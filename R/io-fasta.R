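#' Read a FASTA file into a tibble
#'
#' A minimal validating FASTA reader. Sequences are uppercased and U is
#' converted to T, so genome, reads and references share one DNA alphabet.
#' Multi-line records are concatenated. Malformed input (sequence data
#' before the first header, a header followed by no sequence) raises an
#' error naming the offending line.
#'
#' @param path path to a FASTA file (plain text or gzip).
#' @return a tibble with columns `name` (full header text after `>`)
#'   and `seq`.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgu"), tf)
#' load_fasta(tf)
#' @export
load_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_lines(path)
  keep <- nzchar(trimws(raw))
  lines <- raw[keep]
  line_nos <- which(keep)
  is_header <- startsWith(lines, ">")
  if (length(lines) == 0L || !is_header[1]) {
    abort(sprintf("%s: line 1: expected a '>' FASTA header", path))
  }
  rec <- cumsum(is_header)
  headers <- sub("^>", "", lines[is_header])
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste, character(1), collapse = "")
  # records with no sequence lines are absent from `seqs`
  missing <- setdiff(as.character(seq_along(headers)), names(seqs))
  empty <- names(seqs)[!nzchar(seqs)]
  bad <- suppressWarnings(as.integer(c(missing, empty)))
  if (length(bad) > 0) {
    line_no <- line_nos[which(is_header)[min(bad)]]
    abort(sprintf("%s: line %d: header '%s' has an empty sequence",
                  path, line_no, headers[min(bad)]))
  }
  seqs <- normalize_dna(seqs[as.character(seq_along(headers))])
  assert_alphabet(seqs, what = paste0("FASTA file ", path))
  tibble::tibble(name = headers, seq = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param x a tibble with columns `name` and `seq` (as from [load_fasta()]).
#' @param path output path.
#' @param width line-wrap width; `Inf` writes one line per sequence.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70) {
  out <- purrr::map2(x$name, x$seq, function(nm, sq) {
    body <- if (is.finite(width) && nchar(sq) > width) {
      starts <- seq(1, nchar(sq), by = width)
      substring(sq, starts, pmin(starts + width - 1, nchar(sq)))
    } else sq
    c(paste0(">", nm), body)
  })
  readr::write_lines(unlist(out), path)
  invisible(path)
}

#' Read collapsed small-RNA reads
#'
#' Collapsed-read FASTA uses the de-facto small-RNA dialect in which the
#' header ends in `_x<count>`, e.g. `>r7_x145` for a sequence observed
#' 145 times. Identical sequences appearing under several headers are
#' merged by summing their counts. Reads containing `N` are dropped (a
#' message reports how many), as are reads outside the length bounds.
#'
#' @param path path to a collapsed-read FASTA file.
#' @param min_len,max_len inclusive read-length bounds applied after
#'   loading; small-RNA libraries are conventionally restricted to
#'   16--30 nt.
#' @return a tibble with columns `read_id`, `seq`, `count`, sorted by
#'   decreasing `count` then by sequence.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a_x12", "TGCCAAAGGAGAATTGCCC"), tf)
#' load_collapsed_reads(tf)
#' @export
load_collapsed_reads <- function(path, min_len = 16, max_len = 30) {
  fa <- load_fasta(path)
  m <- stringr::str_match(fa$name, "_x(\\d+)$")
  bad <- which(is.na(m[, 2]))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s: header '%s' does not end in the collapsed-read suffix _x<count>",
      path, fa$name[bad[1]]))
  }
  reads <- tibble::tibble(
    read_id = sub("_x\\d+$", "", fa$name),
    seq = fa$seq,
    count = as.integer(m[, 2])
  )
  if (any(reads$count < 1)) abort("read counts must be >= 1")
  collapse_reads(reads, min_len = min_len, max_len = max_len)
}

#' Read raw FASTQ reads and collapse identical sequences
#'
#' The FASTQ ingestion path performs its own collapsing: each distinct
#' sequence becomes one read whose count is its number of occurrences.
#' Base qualities are ignored.
#'
#' @inheritParams load_collapsed_reads
#' @return a tibble with columns `read_id`, `seq`, `count`.
#' @export
load_fastq_reads <- function(path, min_len = 16, max_len = 30) {
  lines <- readr::read_lines(path)
  if (length(lines) %% 4 != 0) {
    abort(sprintf("%s: FASTQ record count is not a multiple of 4", path))
  }
  seqs <- normalize_dna(lines[seq(2, length(lines), by = 4)])
  reads <- tibble::tibble(read_id = paste0("q", seq_along(seqs)),
                          seq = seqs, count = 1L)
  collapse_reads(reads, min_len = min_len, max_len = max_len)
}

# shared tail of both ingestion paths: drop Ns, merge duplicates,
# apply length bounds, deterministic ordering
collapse_reads <- function(reads, min_len = 16, max_len = 30) {
  has_n <- stringr::str_detect(reads$seq, "N")
  if (any(has_n)) {
    message(sprintf("dropped %d read(s) containing N (%d sequence records)",
                    sum(reads$count[has_n]), sum(has_n)))
    reads <- reads[!has_n, ]
  }
  len <- nchar(reads$seq)
  reads <- reads[len >= min_len & len <= max_len, ]
  reads |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(read_id = .data$read_id[which.max(.data$count)],
                     count = sum(.data$count), .groups = "drop") |>
    dplyr::select("read_id", "seq", "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq)
}

#' Write collapsed reads in the `_x<count>` dialect
#'
#' @param reads a tibble with columns `read_id`, `seq`, `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path) {
  write_fasta(tibble::tibble(
    name = paste0(reads$read_id, "_x", reads$count),
    seq = reads$seq), path, width = Inf)
}
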