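#' Write miRNA loci as GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per locus and child
#' `miRNA` features for the 5p and 3p mature products when their genomic
#' coordinates are known. Internal coordinates are 0-based half-open;
#' GFF3 columns are 1-based inclusive.
#'
#' @param loci a locus tibble as produced by [discover_loci()] (columns
#'   `locus_id`, `chrom`, `start`, `end`, `strand`, `mfe`, and the
#'   `mature_5p`/`mature_3p` coordinate columns where available).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(loci, path) {
  if (anyDuplicated(loci$locus_id)) {
    abort("locus IDs must be unique for GFF3 output")
  }
  header <- "##gff-version 3"
  if (nrow(loci) == 0) {
    readr::write_lines(header, path)
    return(invisible(path))
  }
  fmt <- function(chrom, type, start, end, strand, attrs, score = ".") {
    paste(chrom, "mirloci", type, start + 1L, end, score, strand, ".",
          attrs, sep = "\t")
  }
  rows <- purrr::pmap(loci, function(...) {
    l <- list(...)
    score <- if (!is.null(l$mfe) && is.finite(l$mfe)) format(l$mfe) else "."
    out <- fmt(l$chrom, "miRNA_primary_transcript", l$start, l$end, l$strand,
               paste0("ID=", l$locus_id, ";Name=", l$locus_id), score)
    for (arm in c("5p", "3p")) {
      s <- l[[paste0("mature_", arm, "_start")]]
      e <- l[[paste0("mature_", arm, "_end")]]
      if (!is.null(s) && !is.na(s)) {
        out <- c(out, fmt(l$chrom, "miRNA", s, e, l$strand,
                          paste0("ID=", l$locus_id, "-", arm,
                                 ";Parent=", l$locus_id)))
      }
    }
    out
  })
  readr::write_lines(c(header, unlist(rows)), path)
  invisible(path)
}

#' Read a locus GFF3 back into a tibble
#'
#' Inverse of [write_locus_gff3()] for the features that writer emits.
#'
#' @param path path to a GFF3 file.
#' @return a tibble with one row per `miRNA_primary_transcript`, with
#'   0-based half-open coordinates and mature-arm coordinates where the
#'   file carries child `miRNA` features.
#' @export
load_locus_gff3 <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(locus_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          strand = character(), mfe = double()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  gff <- tibble::tibble(
    chrom = purrr::map_chr(f, 1), type = purrr::map_chr(f, 3),
    start = as.integer(purrr::map_chr(f, 4)) - 1L,
    end = as.integer(purrr::map_chr(f, 5)),
    score = purrr::map_chr(f, 6), strand = purrr::map_chr(f, 7),
    attrs = purrr::map_chr(f, 9)
  )
  attr_val <- function(a, key) {
    stringr::str_match(a, paste0("(?:^|;)", key, "=([^;]+)"))[, 2]
  }
  pri <- gff |>
    dplyr::filter(.data$type == "miRNA_primary_transcript") |>
    dplyr::mutate(locus_id = attr_val(.data$attrs, "ID"),
                  mfe = suppressWarnings(as.numeric(.data$score))) |>
    dplyr::select("locus_id", "chrom", "start", "end", "strand", "mfe")
  kids <- gff |>
    dplyr::filter(.data$type == "miRNA") |>
    dplyr::mutate(parent = attr_val(.data$attrs, "Parent"),
                  arm = stringr::str_match(attr_val(.data$attrs, "ID"),
                                           "([35]p)$")[, 2]) |>
    dplyr::select("parent", "arm", arm_start = "start", arm_end = "end") |>
    tidyr::pivot_wider(names_from = "arm",
                       values_from = c("arm_start", "arm_end"),
                       names_glue = "mature_{arm}_{.value}") |>
    dplyr::rename_with(~ sub("_arm_", "_", .x))
  dplyr::left_join(pri, kids, by = c(locus_id = "parent"))
}
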