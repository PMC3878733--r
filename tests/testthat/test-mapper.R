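test_that("k-mer index finds all occurrences and nothing else", {
  g <- tibble::tibble(name = "g", seq = "ACGTACGTACGT")
  idx <- build_kmer_index(g, k = 8)
  hits <- map_read_exact("ACGTACGT", idx)
  # the query is its own reverse complement, so both strands hit
  expect_equal(hits$start, c(0L, 0L, 4L, 4L))
  expect_equal(hits$strand, c("+", "-", "+", "-"))
  none <- map_read_exact("GGGGGGGG", idx)
  expect_equal(nrow(none), 0L)
  expect_error(build_kmer_index(g, k = 2), "k-mer")
})

test_that("exact mapping reports both strands with correct placement", {
  set.seed(401)
  bg <- mirloci:::random_dna(300, 0.5)
  insert <- "TGCCAAAGGAGAATTGCCCAT"
  g <- tibble::tibble(
    name = "chr1",
    seq = paste0(substr(bg, 1, 100), insert, substr(bg, 101, 200),
                 revcomp(insert), substr(bg, 201, 300)))
  idx <- build_kmer_index(g)
  hits <- map_read_exact(insert, idx)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(100L, 221L))
  expect_equal(hits$strand, c("+", "-"))
  # minus-strand invariant: revcomp of read equals the genome slice
  expect_equal(substr(g$seq, 222, 242), revcomp(insert))
})

test_that("index mapping equals a naive all-positions scan", {
  set.seed(402)
  g <- tibble::tibble(name = c("c1", "c2"),
                      seq = c(mirloci:::random_dna(1200, 0.5),
                              mirloci:::random_dna(800, 0.5)))
  idx <- build_kmer_index(g)
  # mix of planted (guaranteed hits, both strands) and random reads
  planted <- c(
    substr(g$seq[1], 101, 121), substr(g$seq[2], 51, 72),
    revcomp(substr(g$seq[1], 501, 521)), revcomp(substr(g$seq[2], 301, 322)))
  reads <- c(planted,
             vapply(1:150, function(i) mirloci:::random_dna(21, 0.5),
                    character(1)))
  for (rd in reads) {
    expect_equal(as.data.frame(map_read_exact(rd, idx)),
                 as.data.frame(naive_map(rd, g)))
  }
})

test_that("strand symmetry: mapping revcomp reads on revcomp genome", {
  set.seed(403)
  g <- tibble::tibble(name = "c", seq = mirloci:::random_dna(500, 0.5))
  grc <- tibble::tibble(name = "c", seq = revcomp(g$seq))
  idx <- build_kmer_index(g); idxrc <- build_kmer_index(grc)
  L <- nchar(g$seq)
  for (i in 1:20) {
    s <- sample(0:(L - 21), 1)
    rd <- substr(g$seq, s + 1, s + 21)
    a <- map_read_exact(rd, idx)
    b <- map_read_exact(rd, idxrc)
    # mirror coordinates and flip strands back into g's frame
    b2 <- tibble::tibble(chrom = b$chrom, start = L - b$end,
                         end = L - b$start,
                         strand = ifelse(b$strand == "+", "-", "+")) |>
      dplyr::arrange(chrom, start, strand)
    expect_equal(as.data.frame(a), as.data.frame(b2))
  }
})

test_that("reference matching reports every admissible offset", {
  refs <- tibble::tibble(name = "mir", seq = "TGCCAAAGGAGAATTGCCCGT")
  same <- match_reference_set("TGCCAAAGGAGAATTGCCCGT", refs, max_mm = 2)
  expect_true(any(same$offset == 0 & same$mismatches == 0))
  # three substitutions exceed the budget everywhere at offset 0, and
  # shifted offsets misalign further
  three <- "AGCCAAAGGACAATTGCCCGA"
  expect_equal(nrow(match_reference_set(three, refs, max_mm = 2) |>
                      dplyr::filter(offset == 0)), 0L)
  expect_error(match_reference_set("ACGT", refs[0, ], max_mm = 2), "empty")
  expect_error(match_reference_set("ACGT", refs, max_mm = 3), "max_mm")
})

test_that("reference matching equals exhaustive offset enumeration", {
  set.seed(404)
  for (trial in 1:25) {
    read <- mirloci:::random_dna(sample(18:24, 1), 0.5)
    ref <- mirloci:::random_dna(sample(20:22, 1), 0.5)
    # sometimes plant a near-copy so matches actually occur
    if (trial %% 3 == 0) {
      ch <- strsplit(read, "")[[1]]
      p <- sample(seq_along(ch), sample(0:2, 1))
      for (q in p) ch[q] <- sample(c("A", "C", "G", "T"), 1)
      ref <- paste(ch, collapse = "")
    }
    refs <- tibble::tibble(name = "r", seq = ref)
    got <- match_reference_set(read, refs, max_mm = 2)
    # oracle: slide over every offset, count mismatches in the overlap
    rl <- nchar(read); fl <- nchar(ref)
    exp_rows <- list()
    for (o in -(rl - 16):(fl - 16)) {
      i0 <- max(0, o); i1 <- min(fl, o + rl)
      ov <- i1 - i0
      if (ov < 16) next
      mm <- sum(strsplit(substr(ref, i0 + 1, i1), "")[[1]] !=
                  strsplit(substr(read, i0 - o + 1, i1 - o), "")[[1]])
      if (mm <= 2) exp_rows[[length(exp_rows) + 1]] <-
          tibble::tibble(offset = o, overlap = ov, mismatches = mm)
    }
    expected <- dplyr::bind_rows(exp_rows)
    expect_equal(nrow(got), nrow(expected))
    if (nrow(got) > 0) {
      expect_equal(got[, c("offset", "overlap", "mismatches")],
                   dplyr::arrange(expected, offset))
    }
  }
})

test_that("genome mapping agrees with reference matching at zero mismatches", {
  set.seed(405)
  g <- tibble::tibble(name = "c", seq = mirloci:::random_dna(400, 0.5))
  idx <- build_kmer_index(g)
  rd <- substr(g$seq, 101, 121)
  hits <- map_read_exact(rd, idx)
  refmatch <- match_reference_set(rd, g, max_mm = 0)
  # every exact genome placement appears as a zero-mismatch full overlap
  expect_true(all(hits$start[hits$strand == "+"] %in%
                    refmatch$offset[refmatch$mismatches == 0]))
})
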