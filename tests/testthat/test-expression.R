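test_that("window assignment enforces the -3/+5 rule exactly", {
  canonical <- c(10L, 31L)
  mk <- function(s, e) tibble::tibble(start = s, end = e, count = 1L)
  expect_equal(assign_reads_to_mature(mk(10, 31), canonical)$assignment,
               "mature")
  expect_equal(assign_reads_to_mature(mk(7, 31), canonical)$assignment,
               "mature")                         # start at -3
  expect_equal(assign_reads_to_mature(mk(6, 31), canonical)$assignment,
               "other")                          # start at -4
  expect_equal(assign_reads_to_mature(mk(10, 36), canonical)$assignment,
               "mature")                         # end at +5
  expect_equal(assign_reads_to_mature(mk(10, 37), canonical)$assignment,
               "other")                          # end at +6
})

test_that("window assignment equals brute-force interval enumeration", {
  canonical <- c(5L, 26L)
  loop <- c(0L, 3L)
  subints <- tidyr::expand_grid(s = 0:29, e = 0:30) |>
    dplyr::filter(e > s)
  aln <- tibble::tibble(start = subints$s, end = subints$e, count = 1L)
  got <- assign_reads_to_mature(aln, canonical, loop = loop)$assignment
  want <- dplyr::case_when(
    subints$s >= canonical[1] - 3 & subints$e <= canonical[2] + 5 ~ "mature",
    subints$s >= loop[1] & subints$e <= loop[2] ~ "loop",
    .default = "other")
  expect_equal(got, want)
  # the three categories partition the reads
  expect_equal(sort(unique(got)), sort(unique(want)))
})

test_that("RPM is count per million input reads", {
  expect_equal(rpm(500, 1e6), 500)
  expect_equal(rpm(0, 123456), 0)
  # consistency of a reported count/RPM pair: 9559 reads at RPM 3341
  # implies a library of 9559/3341 * 1e6 input reads
  n_lib <- 9559 / 3341 * 1e6
  expect_equal(rpm(9559, n_lib), 3341, tolerance = 1e-9)
  expect_error(rpm(10, 0), "positive")
})

test_that("RPM is invariant under joint doubling and sums correctly", {
  counts <- c(10, 20, 30)
  expect_equal(rpm(counts, 1000), rpm(2 * counts, 2000))
  # sum of RPM over distinct reads = 1e6 * mapped/total
  total <- 5000; mapped <- sum(counts)
  expect_equal(sum(rpm(counts, total)), 1e6 * mapped / total)
})

test_that("fold-change handles ratios, on/off and undefined cases", {
  expect_equal(as.numeric(fold_change(3341, 592)), 3341 / 592,
               tolerance = 1e-6)
  expect_equal(round(3341 / 592), 6)             # "nearly 6"
  expect_equal(fold_change(145, 0), "ON_OFF")
  expect_equal(fold_change(0, 0), "UNDEFINED")
  expect_equal(as.numeric(fold_change(77, 77)), 1)
  # reciprocity for nonzero pairs
  expect_equal(fold_change_num(10, 4) * fold_change_num(4, 10), 1)
})

test_that("arm ratio reproduces the passenger-dominant bookkeeping", {
  expect_equal(arm_ratio(4, 20), 0.2)            # 5p/3p = 5
  expect_equal(arm_ratio(177, 150), 1.18)
  expect_true(is.na(arm_ratio(7, 0)))
})

test_that("antisense counting is strand-aware and flags zero", {
  locus <- tibble::tibble(chrom = "c", strand = "+", start = 100L,
                          end = 170L)
  aln <- tibble::tibble(
    chrom = "c", start = c(110L, 120L, 300L), end = c(131L, 141L, 321L),
    strand = c("+", "-", "-"), count = c(10L, 3L, 99L))
  a <- count_antisense(locus, aln)
  expect_equal(a$sense, 10)
  expect_equal(a$antisense, 3)
  expect_equal(a$ratio, 10 / 3)
  b <- count_antisense(locus, aln[aln$strand == "+", ])
  expect_true(is.na(b$ratio))
})

test_that("profiling recovers planted expression structure", {
  bench <- get_bench1()
  disc <- get_disc1()
  loci <- tidy(disc)
  expr <- profile_loci(loci, bench$reads_a$reads, bench$reads_b$reads,
                       bench$sim$genome,
                       total_a = bench$reads_a$total_input_reads,
                       total_b = bench$reads_b$total_input_reads)
  expect_equal(nrow(expr), 2 * nrow(loci))
  # the on/off locus: reads in A only
  man <- bench$sim$manifest
  onoff <- man[man$mean_b == 0 & man$mean_a > 0, ]
  lid <- loci$locus_id[loci$start < onoff$mature_3p_end[1] &
                         onoff$mature_3p_start[1] < loci$end &
                         loci$strand == onoff$strand[1]]
  row <- expr[expr$locus_id == lid[1] & expr$condition == "A", ]
  expect_gt(row$count_3p, 0)
  expect_equal(unique(expr$fold_change_3p[expr$locus_id == lid[1]]),
               "ON_OFF")
  # planted fold-change ~6 locus recovered within 3 Poisson SD on counts
  l1 <- man[man$locus == 1, ]
  lid1 <- loci$locus_id[loci$start < l1$mature_3p_end &
                          l1$mature_3p_start < loci$end &
                          loci$strand == l1$strand]
  ca <- expr$count_3p[expr$locus_id == lid1[1] & expr$condition == "A"]
  # expectation: guide share of the locus mean, minus antisense (5%)
  # and tailed reads (10%) which do not genome-map
  expected <- l1$mean_a * (41 / 42) * 0.95 * 0.9
  expect_lt(abs(ca - expected), 3 * sqrt(l1$mean_a))
})
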