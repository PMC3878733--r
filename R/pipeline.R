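# end-to-end orchestration: discover -> profile -> isomir -> degradome

# locus-level isomiR profiling across a read table
#' Classify and tabulate isomiRs for every locus arm
#'
#' For each locus and each annotated mature arm, candidate reads are
#' anchored on the precursor (a 12-nt prefix match pre-filters the
#' read table, so non-templated tailed reads that fail genome mapping
#' are still considered) and classified with [classify_isomir()];
#' [tabulate_isomirs()] then yields per-class count fractions.
#'
#' @param loci locus tibble from [discover_loci()].
#' @param reads collapsed reads tibble.
#' @param condition label attached to the output (default `"A"`).
#' @return a list with `records` (per-read classifications, columns
#'   `locus_id`, `arm`, `condition` + [classify_isomir()] fields) and
#'   `table` (per-locus-arm class fractions).
#' @export
isomir_profiles <- function(loci, reads, condition = "A") {
  recs <- purrr::map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    P <- l$seq
    purrr::map(c("5p", "3p"), function(arm) {
      gs <- l[[paste0("mature_", arm, "_start")]]
      ge <- l[[paste0("mature_", arm, "_end")]]
      if (is.na(gs)) return(NULL)
      canonical <- if (l$strand == "+") c(gs - l$start, ge - l$start)
      else c(l$end - ge, l$end - gs)
      # cheap anchor pre-filter: the read's 12-nt prefix must occur on
      # the precursor near the canonical start
      hit <- vapply(reads$seq, function(sq) {
        p <- regexpr(substr(sq, 1, 12), P, fixed = TRUE)[1]
        !is.na(p) && p > 0 &&
          (p - 1) >= canonical[1] - 3 && (p - 1) <= canonical[2]
      }, logical(1))
      if (!any(hit)) return(NULL)
      classify_isomirs(reads[hit, ], canonical, P) |>
        dplyr::mutate(locus_id = l$locus_id, arm = arm,
                      condition = condition, .before = 1)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  tab <- recs |>
    dplyr::group_by(.data$locus_id, .data$arm, .data$condition) |>
    dplyr::group_modify(~ tabulate_isomirs(.x)) |>
    dplyr::ungroup()
  list(records = recs, table = tab)
}

# self-describing TSV: parameter block as comment lines above the header
write_report <- function(df, path, params = list()) {
  hdr <- c(paste0("# mirloci report: ", basename(path)),
           purrr::imap_chr(params, ~ sprintf("# %s=%s", .y,
                                             paste(.x, collapse = ","))))
  readr::write_lines(hdr, path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Run the full discovery-to-degradome pipeline
#'
#' Orchestrates every stage over in-memory tables: pooled two-condition
#' locus discovery, per-condition expression profiling, isomiR
#' classification, and (when transcripts and degradome tags are given)
#' target prediction plus cleavage calling. When `outdir` is set, a
#' report bundle is written: `loci.gff3`, `loci.tsv`,
#' `expression.tsv`, `isomirs.tsv`, `degradome.tsv` and `run_log.txt`,
#' each report carrying its parameter block, so reruns with identical
#' inputs are byte-identical.
#'
#' @param reads_a,reads_b collapsed read tibbles for the two
#'   conditions.
#' @param genome genome tibble.
#' @param mature_refs reference mature set (family mode) or `NULL`
#'   (de-novo mode).
#' @param transcripts,tags optional transcript and degradome tag
#'   tibbles.
#' @param condition_a,condition_b labels.
#' @param total_a,total_b library input totals; default to the summed
#'   counts.
#' @param outdir optional output directory for the report bundle.
#' @param ... passed to [discover_loci()] (thresholds).
#' @return a `mirloci_run` list: `discovery`, `loci`, `expression`,
#'   `isomirs`, `targets`, `cleavage`, `params`.
#' @export
run_pipeline <- function(reads_a, reads_b, genome, mature_refs = NULL,
                         transcripts = NULL, tags = NULL,
                         condition_a = "A", condition_b = "B",
                         total_a = sum(reads_a$count),
                         total_b = sum(reads_b$count),
                         outdir = NULL, ...) {
  mode <- if (is.null(mature_refs)) "denovo" else "family"
  pooled <- dplyr::bind_rows(reads_a, reads_b) |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(read_id = .data$read_id[1], count = sum(.data$count),
                     .groups = "drop") |>
    dplyr::select("read_id", "seq", "count")
  if (nrow(pooled) == 0) {
    warn("no reads supplied; returning an empty result")
    return(structure(list(discovery = NULL, loci = tibble::tibble(),
                          expression = tibble::tibble(),
                          isomirs = tibble::tibble(),
                          targets = tibble::tibble(),
                          cleavage = tibble::tibble(),
                          params = list(mode = mode)),
                     class = "mirloci_run"))
  }
  disc <- discover_loci(pooled, genome, mature_refs = mature_refs,
                        mode = mode, ...)
  loci <- disc$loci
  expr <- if (nrow(loci) > 0) {
    profile_loci(loci, reads_a, reads_b, genome,
                 condition_a = condition_a, condition_b = condition_b,
                 total_a = total_a, total_b = total_b)
  } else tibble::tibble()
  iso <- if (nrow(loci) > 0) {
    dplyr::bind_rows(
      isomir_profiles(loci, reads_a, condition = condition_a)$table,
      isomir_profiles(loci, reads_b, condition = condition_b)$table)
  } else tibble::tibble()

  targets <- tibble::tibble(); cleavage <- tibble::tibble()
  if (!is.null(transcripts) && nrow(loci) > 0) {
    mirnas <- loci |>
      dplyr::filter(!is.na(.data$mature_3p_seq)) |>
      dplyr::distinct(.data$mature_3p_seq, .keep_all = TRUE) |>
      dplyr::transmute(name = .data$locus_id, seq = .data$mature_3p_seq)
    targets <- predict_targets_set(mirnas, transcripts)
    if (!is.null(tags) && nrow(targets) > 0) {
      cleavage <- call_cleavage(targets, tags, transcripts)
    }
  }

  params <- c(disc$params,
              list(condition_a = condition_a, condition_b = condition_b,
                   total_a = total_a, total_b = total_b))
  run <- structure(list(discovery = disc, loci = loci, expression = expr,
                        isomirs = iso, targets = targets,
                        cleavage = cleavage, params = params),
                   class = "mirloci_run")
  if (!is.null(outdir)) write_run_bundle(run, outdir)
  run
}

# serialize the report bundle
write_run_bundle <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- run$params
  pb <- p[vapply(p, function(x) is.atomic(x) && length(x) == 1, logical(1))]
  loci_flat <- run$loci
  write_locus_gff3(loci_flat, file.path(outdir, "loci.gff3"))
  write_report(loci_flat, file.path(outdir, "loci.tsv"), pb)
  write_report(run$expression, file.path(outdir, "expression.tsv"), pb)
  write_report(run$isomirs, file.path(outdir, "isomirs.tsv"), pb)
  if (nrow(run$cleavage) > 0) {
    write_report(run$cleavage, file.path(outdir, "degradome.tsv"), pb)
  }
  stats <- if (!is.null(run$discovery)) run$discovery$stats else list()
  readr::write_lines(c(
    paste0("mirloci ", as.character(utils::packageVersion("mirloci"))),
    purrr::imap_chr(pb, ~ sprintf("param %s=%s", .y, .x)),
    purrr::imap_chr(stats, ~ sprintf("stat %s=%s", .y, .x))),
    file.path(outdir, "run_log.txt"))
  invisible(outdir)
}

#' @export
print.mirloci_run <- function(x, ...) {
  cat(sprintf("<mirloci_run> %d loci, %d expression rows, %d cleavage calls\n",
              nrow(x$loci), nrow(x$expression), nrow(x$cleavage)))
  invisible(x)
}
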