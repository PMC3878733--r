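test_that("target scoring applies the penalty table with core doubling", {
  mir <- "TGCCGAAGGAGAATTGCCCGT"     # G at position 5, so a wobble fits
  perfect <- revcomp(mir)
  expect_equal(score_target_alignment(mir, perfect)$penalty, 0)

  # one G:U at miRNA position 5 (core, x2) plus a mismatch at 18
  ch <- strsplit(perfect, "")[[1]]
  n <- nchar(mir)
  mirch <- strsplit(mir, "")[[1]]
  # window base facing miRNA position p sits at reversed index p
  gu_pos <- n - 5 + 1
  ch[gu_pos] <- if (mirch[5] == "G") "T" else "G"   # make a wobble
  mm_pos <- n - 18 + 1
  ch[mm_pos] <- setdiff(c("A", "C", "G", "T"),
                        c(ch[mm_pos], chartr("ACGT", "TGCA", mirch[18]),
                          if (mirch[18] == "G") "T",
                          if (mirch[18] == "T") "G"))[1]
  win <- paste(ch, collapse = "")
  res <- score_target_alignment(mir, win)
  expect_equal(res$penalty, 0.5 * 2 + 1.0)
  expect_equal(res$states[5], "GU")
  expect_equal(res$states[18], "mismatch")
})

test_that("scoring equals exhaustive alignment enumeration", {
  set.seed(801)
  for (trial in 1:10) {
    n <- sample(20:22, 1)
    mir <- mirloci:::random_dna(n, 0.5)
    for (w in (n - 1):(n + 1)) {
      win <- mirloci:::random_dna(w, 0.5)
      expect_equal(score_target_alignment(mir, win)$penalty,
                   oracle_target_penalty(mir, win))
    }
    # near-complementary windows too, where gaps actually matter
    ch <- strsplit(revcomp(mir), "")[[1]]
    ins <- sample(seq_along(ch), 1)
    win_ins <- paste(append(ch, sample(c("A", "C", "G", "T"), 1), ins),
                     collapse = "")
    expect_equal(score_target_alignment(mir, win_ins)$penalty,
                 oracle_target_penalty(mir, win_ins))
    win_del <- paste(ch[-ins], collapse = "")
    expect_equal(score_target_alignment(mir, win_del)$penalty,
                 oracle_target_penalty(mir, win_del))
  }
  expect_error(score_target_alignment("ACGTACGTACGTACGTACGTA",
                                      "ACGTACGTACGTACGTACG"),
               "within one")
})

test_that("target prediction finds planted sites and respects the cutoff", {
  set.seed(802)
  mir <- "TGCCAAAGGAGAATTGCCCGT"
  site <- revcomp(mir)
  tx <- paste0(mirloci:::random_dna(100, 0.5), site,
               mirloci:::random_dna(80, 0.5), site,
               mirloci:::random_dna(60, 0.5))
  hits <- predict_targets(mir, tibble::tibble(name = "t", seq = tx))
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$start, c(100L, 201L))
  expect_equal(hits$penalty, c(0, 0))

  scram <- tibble::tibble(
    name = "s", seq = paste(sample(strsplit(tx, "")[[1]]), collapse = ""))
  expect_equal(nrow(predict_targets(mir, scram)), 0L)

  # monotonicity: raising the cutoff never removes sites
  lo <- predict_targets(mir, tibble::tibble(name = "t", seq = tx),
                        max_penalty = 1)
  hi <- predict_targets(mir, tibble::tibble(name = "t", seq = tx),
                        max_penalty = 5)
  expect_true(all(paste(lo$start, lo$end) %in% paste(hi$start, hi$end)))
})

test_that("prediction is stable under transcript concatenation", {
  set.seed(803)
  mir <- mirloci:::random_dna(21, 0.5)
  t1 <- paste0(mirloci:::random_dna(60, 0.5), revcomp(mir),
               mirloci:::random_dna(40, 0.5))
  t2 <- paste0(mirloci:::random_dna(30, 0.5), revcomp(mir),
               mirloci:::random_dna(50, 0.5))
  sep <- predict_targets(mir, tibble::tibble(name = c("a", "b"),
                                             seq = c(t1, t2)))
  cat_ <- predict_targets(mir, tibble::tibble(name = "ab",
                                              seq = paste0(t1, t2)))
  shifted <- c(sep$start[sep$transcript == "a"],
               sep$start[sep$transcript == "b"] + nchar(t1))
  expect_true(all(shifted %in% cat_$start))
})

test_that("cleavage calls map the 5'-end pileup to miRNA coordinates", {
  set.seed(804)
  mir <- "TGCCAAAGGAGAATTGCCCGT"
  site <- revcomp(mir)
  tx <- paste0(mirloci:::random_dna(150, 0.45), site,
               mirloci:::random_dna(120, 0.45))
  sites <- predict_targets(mir, tibble::tibble(name = "t", seq = tx),
                           mirna_id = "m")
  s <- sites[1, ]
  canon_pos <- s$end - 10L
  mk_tags <- function(pos, counts) tibble::tibble(
    read_id = paste0("t", seq_along(pos)),
    seq = substring(tx, pos + 1, pos + 20), count = counts)

  call <- pileup_and_call(s, mk_tags(rep(canon_pos, 3), c(50L, 1L, 1L)), tx)
  expect_equal(call$relative_pos, 10L)
  expect_equal(call$category, "canonical_10_11")
  expect_false(call$low_confidence)

  off <- pileup_and_call(s, mk_tags(rep(s$end - 14L, 2), c(40L, 2L)), tx)
  expect_equal(off$relative_pos, 14L)
  expect_equal(off$category, "other")

  # uniform background over the site: flagged low confidence
  unif <- pileup_and_call(s, mk_tags(s$start:(s$end - 1),
                                     rep(2L, s$end - s$start)), tx)
  expect_true(unif$low_confidence)

  # no tags in the site
  expect_null(pileup_and_call(s, mk_tags(5L, 10L), tx))
})

test_that("relative-position arithmetic holds over the whole site", {
  set.seed(805)
  mir <- mirloci:::random_dna(21, 0.5)
  tx <- paste0(mirloci:::random_dna(90, 0.45), revcomp(mir),
               mirloci:::random_dna(90, 0.45))
  s <- predict_targets(mir, tibble::tibble(name = "t", seq = tx),
                       mirna_id = "m")[1, ]
  # a tag starting at the nt paired with miRNA position p reports p
  for (p in c(1L, 10L, 11L, 21L)) {
    pos <- s$end - p
    tag <- tibble::tibble(read_id = "x",
                          seq = substr(tx, pos + 1, pos + 20), count = 5L)
    call <- pileup_and_call(s, tag, tx)
    expect_equal(call$relative_pos, p)
    expect_equal(call$category,
                 if (p %in% c(10, 11)) "canonical_10_11" else "other")
  }
})
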