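# helpers building a one-locus genome with hand-placed reads

toy_genome_with_hairpin <- function(seed = 21) {
  set.seed(seed)
  hp <- mirloci:::design_hairpin(21)
  left <- mirloci:::random_dna(200, 0.45)
  right <- mirloci:::random_dna(200, 0.45)
  genome <- tibble::tibble(name = "chr1",
                           seq = paste0(left, hp$full, right))
  g0 <- 200L
  L <- nchar(hp$full)
  list(genome = genome, hp = hp, g0 = g0,
       m5 = c(g0 + 2L, g0 + 23L),
       m3 = c(g0 + L - 21L, g0 + L))
}

reads_at <- function(genome, intervals, counts) {
  g <- genome$seq[1]
  tibble::tibble(
    read_id = paste0("r", seq_along(counts)),
    seq = vapply(intervals, function(iv) substr(g, iv[1] + 1, iv[2]),
                 character(1)),
    count = as.integer(counts))
}

test_that("precursor extraction spans the cluster pair on either strand", {
  toy <- toy_genome_with_hairpin()
  reads <- reads_at(toy$genome, list(toy$m5, toy$m3), c(50, 40))
  idx <- build_kmer_index(toy$genome)
  aln <- map_reads(reads, idx)
  cl <- cluster_reads(aln)
  pr <- pair_clusters(cl)
  expect_equal(nrow(pr), 1L)
  cand <- extract_precursor(pr[1, ], cl, toy$genome)
  expect_equal(cand$start, toy$m5[1])
  expect_equal(cand$end, toy$m3[2])
  expect_equal(nchar(cand$seq), toy$m3[2] - toy$m5[1])
  expect_equal(cand$arm_5p, c(0L, 21L))

  # configurable flank grows the span on both sides
  flanked <- extract_precursor(pr[1, ], cl, toy$genome, flank = 10)
  expect_equal(flanked$start, toy$m5[1] - 10L)
  expect_equal(flanked$end, toy$m3[2] + 10L)

  # minus strand: the candidate is the reverse complement of the span
  rc_genome <- tibble::tibble(name = "chr1", seq = revcomp(toy$genome$seq))
  idx2 <- build_kmer_index(rc_genome)
  aln2 <- map_reads(reads, idx2)
  expect_true(all(aln2$strand == "-"))
  cl2 <- cluster_reads(aln2)
  pr2 <- pair_clusters(cl2)
  cand2 <- extract_precursor(pr2[1, ], cl2, rc_genome)
  expect_equal(cand2$seq, cand$seq)
  expect_equal(cand2$strand, "-")
})

test_that("a planted hairpin with homogeneous reads passes every filter", {
  toy <- toy_genome_with_hairpin()
  reads <- reads_at(toy$genome,
                    list(toy$m5, toy$m3,
                         c(toy$m3[1], toy$m3[2] + 2L)),   # 3' isomiR
                    c(50, 45, 5))
  idx <- build_kmer_index(toy$genome)
  cl <- cluster_reads(map_reads(reads, idx))
  pr <- pair_clusters(cl)
  cand <- extract_precursor(pr[1, ], cl, toy$genome)
  cand$fold <- fold_mfe(cand$seq)
  refs <- tibble::tibble(name = "ref", seq = substr(
    toy$genome$seq, toy$m3[1] + 1, toy$m3[2]))
  v <- validate_candidate(cand, refs)
  expect_true(v$verdict$accepted)
  expect_equal(v$verdict$reasons, character(0))
  expect_equal(v$verdict$family, "ref")
})

test_that("a non-folding decoy fails with the MFE code", {
  set.seed(22)
  genome <- tibble::tibble(
    name = "chr1", seq = mirloci:::random_dna(400, 0.15))
  iv1 <- c(100L, 121L); iv2 <- c(180L, 201L)
  reads <- reads_at(genome, list(iv1, iv2), c(30, 25))
  idx <- build_kmer_index(genome)
  cl <- cluster_reads(map_reads(reads, idx))
  pr <- pair_clusters(cl)
  cand <- extract_precursor(pr[1, ], cl, genome)
  cand$fold <- fold_mfe(cand$seq)
  v <- validate_candidate(cand, mode = "denovo")
  expect_false(v$verdict$accepted)
  expect_true("MFE" %in% v$verdict$reasons)
})

test_that("uniform 5' fluctuation fails the homogeneity filter", {
  toy <- toy_genome_with_hairpin()
  # 6 equally frequent 5' offsets on the 5p arm: modal fraction ~ 1/6
  ivs5 <- lapply(0:5, function(d) c(toy$m5[1] + d - 3L, toy$m5[2] + d - 3L))
  reads <- reads_at(toy$genome, c(ivs5, list(toy$m3)), c(rep(10, 6), 40))
  idx <- build_kmer_index(toy$genome)
  cl <- cluster_reads(map_reads(reads, idx))
  pr <- pair_clusters(cl)
  expect_equal(nrow(pr), 1L)
  cand <- extract_precursor(pr[1, ], cl, toy$genome)
  cand$fold <- fold_mfe(cand$seq)
  v <- validate_candidate(cand, mode = "denovo")
  # enumerated modal fraction: 10 of 60 reads share the modal start
  expect_equal(v$verdict$five_prime_fraction, 1 / 6)
  expect_true("FIVE_PRIME" %in% v$verdict$reasons)
})

test_that("an unfolded candidate is a state error", {
  toy <- toy_genome_with_hairpin()
  reads <- reads_at(toy$genome, list(toy$m5, toy$m3), c(5, 5))
  idx <- build_kmer_index(toy$genome)
  cl <- cluster_reads(map_reads(reads, idx))
  pr <- pair_clusters(cl)
  cand <- extract_precursor(pr[1, ], cl, toy$genome)
  expect_error(validate_candidate(cand, mode = "denovo"), "folded")
})

test_that("homology expansion finds additional hairpin copies only", {
  set.seed(23)
  hp <- mirloci:::design_hairpin(21)
  mature <- substr(hp$full, nchar(hp$full) - 20, nchar(hp$full))
  spacer <- function(n) mirloci:::random_dna(n, 0.45)
  # copy 1 and 2 inside hairpins, copy 3 as a bare mature (no hairpin)
  genome <- tibble::tibble(name = "chr1", seq = paste0(
    spacer(150), hp$full, spacer(300), hp$full, spacer(300),
    mature, spacer(150)))
  loci <- homology_expand(mature, genome)
  expect_equal(nrow(loci), 2L)
  expect_true(all(loci$source == "homology_expanded"))
  expect_true(all(loci$mfe <= -35))

  # a mature absent from the genome expands to nothing
  none <- homology_expand(strrep("ACGTT", 5), genome)
  expect_equal(nrow(none), 0L)

  # placements already inside known loci are not re-reported
  existing <- tibble::tibble(chrom = "chr1", strand = "+",
                             start = loci$start, end = loci$end)
  again <- homology_expand(mature, genome, existing = existing)
  expect_equal(nrow(again), 0L)
})

test_that("benchmark discovery names shared-mature gene copies", {
  disc <- get_disc1()
  loci <- tidy(disc)
  shared <- loci |>
    dplyr::group_by(mature_3p_seq) |>
    dplyr::filter(dplyr::n() > 1)
  expect_gt(nrow(shared), 0)
  expect_true(all(grepl("-[0-9]+$", shared$locus_id)))
  expect_equal(dplyr::n_distinct(sub("-[0-9]+$", "", shared$locus_id)),
               dplyr::n_distinct(shared$mature_3p_seq))
})
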