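# a small fixed precursor for classification tests: canonical mature at
# [10, 31), with known downstream bases for tail logic
PREC <- paste0("AAAACCAAGG",                 # 0-9
               "TGCCAAAGGAGAATTGCCCGT",      # canonical, 10-30
               "GAAACAAACCAAACCAAACC")       # downstream template: G at 31
CANON <- c(10L, 31L)
CANON_SEQ <- substr(PREC, 11, 31)

test_that("canonical reads classify as canonical", {
  r <- classify_isomir(CANON_SEQ, 5L, CANON, PREC)
  expect_true(r$accepted)
  expect_equal(r$offset_5p, 0L)
  expect_equal(r$offset_3p_templated, 0L)
  expect_equal(r$tail_class, "none")
  expect_equal(r$internal_mismatches, 0L)
})

test_that("non-templated tails are distinguished from templated extensions", {
  # template after the canonical end is G, so +A is non-templated
  r <- classify_isomir(paste0(CANON_SEQ, "A"), 1L, CANON, PREC)
  expect_equal(r$tail_class, "adenylated")
  expect_equal(r$nta_tail, "A")
  expect_equal(r$offset_3p_templated, 0L)

  rt <- classify_isomir(paste0(CANON_SEQ, "T"), 1L, CANON, PREC)
  expect_equal(rt$tail_class, "uridylated")

  # +G matches the template: a templated 3' extension, not an NTA
  rg <- classify_isomir(paste0(CANON_SEQ, "G"), 1L, CANON, PREC)
  expect_equal(rg$tail_class, "none")
  expect_equal(rg$offset_3p_templated, 1L)
})

test_that("5' truncations are reported as positive offsets", {
  r <- classify_isomir(substr(CANON_SEQ, 4, 21), 1L, CANON, PREC)
  expect_equal(r$offset_5p, 3L)
  expect_equal(r$offset_3p_templated, 0L)
  expect_equal(r$tail_class, "none")
})

test_that("reads outside the isomiR window are rejected with a reason", {
  far <- substr(PREC, 36, 56)
  r <- classify_isomir(far, 1L, CANON, PREC)
  expect_false(r$accepted)
  expect_match(r$reason, "window")
})

test_that("classification agrees with exhaustive decomposition", {
  set.seed(701)
  reads <- list()
  for (i in 1:120) {
    d5 <- sample(-3:5, 1)
    d3 <- sample(-3:3, 1)
    s <- CANON[1] + d5; e <- CANON[2] + d3
    if (s < 0 || e > nchar(PREC) || e - s < 16 || e > CANON[2] + 5) next
    sq <- substr(PREC, s + 1, e)
    kind <- sample(c("plain", "tail", "sub"), 1)
    if (kind == "tail") {
      tl <- sample(1:2, 1)
      tail <- paste(sample(c("A", "T"), tl, replace = TRUE), collapse = "")
      sq <- paste0(sq, tail)
    } else if (kind == "sub") {
      ch <- strsplit(sq, "")[[1]]
      p <- sample(2:(length(ch) - 1), 1)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      sq <- paste(ch, collapse = "")
    }
    reads[[length(reads) + 1]] <- sq
  }
  for (sq in unique(unlist(reads))) {
    got <- classify_isomir(sq, 1L, CANON, PREC)
    want <- oracle_isomir(sq, CANON, PREC)
    if (is.null(want)) {
      expect_false(got$accepted)
    } else {
      expect_true(got$accepted)
      expect_equal(got$offset_5p, want$s - CANON[1])
      expect_equal(got$offset_3p_templated, (want$s + want$tl) - CANON[2])
      expect_equal(got$nta_tail, want$tail)
      expect_equal(got$internal_mismatches, want$mm)
    }
  }
})

test_that("an adenylated call never has a templated A at the tail", {
  cfg <- sim_config(seed = 31, n_decoys = 0, n_background = 0,
                    nta_rate_a = 0.15, nta_rate_u = 0.1,
                    antisense_rate = 0, loop_read_rate = 0,
                    loci = tibble::tibble(
                      locus = 1L, strand = "+", mean_a = 400,
                      mean_b = 0, arm_ratio_3p5p = 2,
                      shares_mature_with = NA_integer_))
  sim <- simulate_genome(cfg)
  man <- sim$manifest
  reads <- simulate_reads(sim, "A")$reads
  loci <- tibble::tibble(
    locus_id = "L1", seq = man$prec_seq,
    strand = "+", start = man$start, end = man$end,
    mature_5p_seq = man$mature_5p_seq,
    mature_3p_seq = man$mature_3p_seq,
    mature_5p_start = man$mature_5p_start,
    mature_5p_end = man$mature_5p_end,
    mature_3p_start = man$mature_3p_start,
    mature_3p_end = man$mature_3p_end)
  prof <- isomir_profiles(loci, reads)
  recs <- prof$records[prof$records$accepted &
                         prof$records$tail_class == "adenylated", ]
  expect_gt(nrow(recs), 0)
  if (nrow(recs) > 0) {
    for (i in seq_len(nrow(recs))) {
      # reconstruct: templated part + tail must equal the read, and the
      # first tail base must differ from the template
      r <- recs[i, ]
      canon <- if (r$arm == "3p") {
        c(loci$mature_3p_start - loci$start, loci$mature_3p_end - loci$start)
      } else {
        c(loci$mature_5p_start - loci$start, loci$mature_5p_end - loci$start)
      }
      s <- canon[1] + r$offset_5p
      tl_end <- canon[2] + r$offset_3p_templated
      tmpl <- substr(loci$seq, s + 1, tl_end)
      expect_equal(paste0(tmpl, r$nta_tail), r$seq)
      nxt <- substr(loci$seq, tl_end + 1, tl_end + 1)
      expect_false(nxt == substr(r$nta_tail, 1, 1))
    }
  }
})

test_that("isomiR tabulation fractions partition to one", {
  recs <- dplyr::bind_rows(
    classify_isomir(CANON_SEQ, 90L, CANON, PREC),
    classify_isomir(paste0(CANON_SEQ, "T"), 10L, CANON, PREC))
  tab <- tabulate_isomirs(recs)
  expect_equal(sum(tab$fraction), 1)
  expect_equal(tab$fraction[tab$class == "uridylated"], 0.10)

  single <- tabulate_isomirs(classify_isomir(CANON_SEQ, 3L, CANON, PREC))
  expect_equal(single$fraction, 1)

  expect_equal(nrow(tabulate_isomirs(recs[0, ])), 0L)
})

test_that("count conservation: classified + rejected = assigned", {
  set.seed(703)
  reads <- tibble::tibble(
    seq = c(CANON_SEQ, paste0(CANON_SEQ, "A"), substr(PREC, 36, 56)),
    count = c(50L, 5L, 9L))
  recs <- classify_isomirs(reads, CANON, PREC)
  expect_equal(sum(recs$count), sum(reads$count))
  expect_equal(sum(recs$count[recs$accepted]), 55L)
  expect_equal(sum(recs$count[!recs$accepted]), 9L)
})

test_that("alternative duplexes require 2-nt overhangs on both strands", {
  # long perfect stem so a shifted duplex stays clear of loop and ends:
  # pairing i <-> 77-i; a 21-nt mature at [4,25) partners [55,76) for
  # 2-nt 3' overhangs, and shifting the pair +4/-4 along the stem
  # preserves the overhang geometry
  set.seed(704)
  arm <- mirloci:::random_dna(30, 0.6)
  loop <- paste(sample(c("A", "C"), 18, TRUE, prob = c(0.6, 0.4)),
                collapse = "")
  hp <- paste0(arm, loop, revcomp(arm))
  f <- fold_mfe(hp)
  canon5 <- c(4L, 25L); canon3 <- c(55L, 76L)
  alt5 <- canon5 + 4L; alt3 <- canon3 - 4L
  mk_members <- function(with_alt = FALSE) {
    m <- tibble::tibble(
      arm = c("5p", "3p"),
      prec_start = c(canon5[1], canon3[1]),
      prec_end = c(canon5[2], canon3[2]),
      count = c(10L, 12L))
    if (with_alt) {
      m <- dplyr::bind_rows(m, tibble::tibble(
        arm = c("5p", "3p"),
        prec_start = c(alt5[1], alt3[1]),
        prec_end = c(alt5[2], alt3[2]),
        count = c(4L, 5L)))
    }
    m
  }
  only_canon <- detect_alternative_duplex(mk_members(), f,
                                          canonical_5p = canon5,
                                          canonical_3p = canon3)
  expect_equal(nrow(only_canon), 1L)
  expect_true(only_canon$canonical)

  with_alt <- detect_alternative_duplex(mk_members(TRUE), f,
                                        canonical_5p = canon5,
                                        canonical_3p = canon3)
  expect_equal(nrow(with_alt), 2L)
  expect_equal(sum(with_alt$canonical), 1L)
  alt_row <- with_alt[!with_alt$canonical, ]
  expect_equal(alt_row$overhang_5p, 2L)
  expect_equal(alt_row$overhang_3p, 2L)

  # a shifted pair with mismatched overhangs is not reported: move only
  # the 3p arm by one, giving (1,2)-style overhangs
  skew <- dplyr::bind_rows(
    mk_members(),
    tibble::tibble(arm = c("5p", "3p"),
                   prec_start = c(alt5[1], alt3[1] + 1L),
                   prec_end = c(alt5[2], alt3[2] + 1L),
                   count = c(4L, 5L)))
  got <- detect_alternative_duplex(skew, f, canonical_5p = canon5,
                                   canonical_3p = canon3)
  expect_equal(nrow(got), 1L)       # only the canonical pair survives
})
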