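#' Greedy count-ordered clustering of mapped reads
#'
#' Implements the read-cluster construction used for miRNA locus
#' discovery: alignments are visited in decreasing read-count order
#' (ties broken by chromosome, start, strand, then sequence); the first
#' alignment seeds a cluster whose coordinates are its own and never
#' change; every subsequent alignment joins the first existing cluster
#' (in creation order) whose window `[cluster_start - 3, cluster_end + 5]`
#' on the same chromosome and strand fully contains it, and otherwise
#' seeds a new cluster. The asymmetric flanks admit the same isomiR
#' window used downstream, so length and end variants of a mature
#' sequence fall into the cluster of its most abundant form.
#'
#' @param alignments tibble of exact alignments with columns `read_id`,
#'   `seq`, `count`, `chrom`, `start`, `end`, `strand` (as from
#'   [map_reads()]).
#' @param flank_up,flank_down window flanks upstream of the cluster
#'   start and downstream of the cluster end (defaults 3 and 5).
#' @return a tibble of clusters: `cluster_id`, `chrom`, `strand`,
#'   `start`, `end` (the seed read's coordinates), `seed_seq`,
#'   `n_members`, `total_count`, and a list-column `members` holding
#'   each cluster's alignments. Every alignment belongs to exactly one
#'   cluster.
#' @export
cluster_reads <- function(alignments, flank_up = 3, flank_down = 5) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(cluster_id = integer(), chrom = character(),
                          strand = character(), start = integer(),
                          end = integer(), seed_seq = character(),
                          n_members = integer(), total_count = integer(),
                          members = list()))
  }
  aln <- alignments |>
    dplyr::arrange(dplyr::desc(.data$count), .data$chrom, .data$start,
                   .data$strand, .data$seq)
  n <- nrow(aln)
  # cluster registers (grown geometrically would be overkill at this scale)
  c_chrom <- character(0); c_strand <- character(0)
  c_start <- integer(0); c_end <- integer(0)
  assignment <- integer(n)
  for (r in seq_len(n)) {
    ch <- aln$chrom[r]; st <- aln$strand[r]
    s <- aln$start[r]; e <- aln$end[r]
    hit <- which(c_chrom == ch & c_strand == st &
                   c_start - flank_up <= s & e <= c_end + flank_down)
    if (length(hit) > 0) {
      assignment[r] <- hit[1]                 # first cluster in creation order
    } else {
      c_chrom <- c(c_chrom, ch); c_strand <- c(c_strand, st)
      c_start <- c(c_start, s); c_end <- c(c_end, e)
      assignment[r] <- length(c_start)
    }
  }
  members <- split(aln, assignment)
  ids <- as.integer(names(members))
  members <- unname(members)
  tibble::tibble(
    cluster_id = ids,
    chrom = c_chrom[ids], strand = c_strand[ids],
    start = c_start[ids], end = c_end[ids],
    seed_seq = purrr::map_chr(members, ~ .x$seq[1]),
    n_members = purrr::map_int(members, nrow),
    total_count = purrr::map_int(members, ~ sum(.x$count)),
    members = members
  ) |>
    dplyr::arrange(.data$cluster_id)
}

#' Pair read clusters into pre-miRNA candidates
#'
#' All ordered pairs of non-overlapping clusters on the same chromosome
#' and strand whose inner gap (end of the upstream cluster to start of
#' the downstream one) is strictly less than `max_gap` nucleotides. A
#' cluster may take part in several pairs.
#'
#' @param clusters a [cluster_reads()] tibble.
#' @param max_gap maximum inner distance in nt (strict `<`; default 150,
#'   the spacing expected between the two arms of a plant pre-miRNA).
#' @return tibble with columns `cluster_a` (upstream id), `cluster_b`,
#'   `chrom`, `strand`, `gap`.
#' @export
pair_clusters <- function(clusters, max_gap = 150) {
  if (nrow(clusters) < 2) {
    return(tibble::tibble(cluster_a = integer(), cluster_b = integer(),
                          chrom = character(), strand = character(),
                          gap = integer()))
  }
  a <- clusters |>
    dplyr::select(cluster_a = "cluster_id", "chrom", "strand",
                  a_start = "start", a_end = "end")
  b <- clusters |>
    dplyr::select(cluster_b = "cluster_id", "chrom", "strand",
                  b_start = "start", b_end = "end")
  dplyr::inner_join(a, b, by = c("chrom", "strand"),
                    relationship = "many-to-many") |>
    dplyr::filter(.data$cluster_a != .data$cluster_b,
                  .data$a_end <= .data$b_start) |>        # upstream, no overlap
    dplyr::mutate(gap = .data$b_start - .data$a_end) |>
    dplyr::filter(.data$gap < max_gap) |>
    dplyr::select("cluster_a", "cluster_b", "chrom", "strand", "gap") |>
    dplyr::arrange(.data$chrom, .data$strand, .data$cluster_a, .data$cluster_b)
}
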