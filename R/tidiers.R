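# broom-style tidiers for the pipeline's fitted objects

#' Tidy a discovery result into its locus table
#'
#' @param x a `mirna_discovery` object.
#' @param ... unused.
#' @return the accepted-locus tibble (one row per locus).
#' @export
tidy.mirna_discovery <- function(x, ...) x$loci

#' One-row summary of a discovery run
#'
#' @param x a `mirna_discovery` object.
#' @param ... unused.
#' @return a one-row tibble: read/cluster/pair/candidate tallies,
#'   accepted loci split by source, and the thresholds used.
#' @export
glance.mirna_discovery <- function(x, ...) {
  tibble::tibble(
    n_reads = x$stats$n_reads,
    n_read_count = x$stats$n_read_count,
    n_mapped = x$stats$n_mapped,
    n_clusters = x$stats$n_clusters,
    n_pairs = x$stats$n_pairs,
    n_candidates_accepted = x$stats$n_accepted,
    n_loci = nrow(x$loci),
    n_de_novo = sum(x$loci$source == "de_novo"),
    n_homology = sum(x$loci$source == "homology_expanded"),
    mode = x$params$mode,
    mfe_max = x$params$mfe_max,
    max_gap = x$params$max_gap)
}

#' @export
tidy.mirloci_run <- function(x, ...) x$loci

#' @export
glance.mirloci_run <- function(x, ...) {
  tibble::tibble(
    n_loci = nrow(x$loci),
    n_expression_rows = nrow(x$expression),
    n_isomir_rows = nrow(x$isomirs),
    n_target_sites = nrow(x$targets),
    n_cleavage_calls = nrow(x$cleavage))
}

#' @export
tidy.fold_result <- function(x, ...) {
  partner <- pair_table(x$structure)
  tibble::tibble(pos = seq_along(partner) - 1L,
                 base = strsplit(x$seq, "")[[1]],
                 state = strsplit(x$structure, "")[[1]],
                 partner = partner)
}

#' @export
glance.fold_result <- function(x, ...) {
  tibble::tibble(length = nchar(x$seq), mfe = x$mfe,
                 n_pairs = sum(strsplit(x$structure, "")[[1]] == "("))
}
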