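# deterministic seeded generator of genomes, two-condition sRNA
# libraries and degradome tags; the benchmark stand-in for a real
# two-condition small-RNA study

#' Simulation configuration
#'
#' Builds the configuration for the synthetic benchmark. The defaults
#' describe the "study-like" study design this package is benchmarked
#' on: twelve planted pre-miRNA hairpin loci (one expressed in
#' condition A only; one passenger-dominant with 5p/3p mean counts
#' 20/4; two genes ~2000 nt apart sharing one mature sequence; three
#' on the minus strand) and eight decoy read-cluster pairs over
#' non-folding AT-rich sequence. Counts are drawn Poisson around the
#' configured means - the simplest noise model consistent with library
#' sampling. All randomness flows through R's default Mersenne-Twister
#' generator seeded from `seed`.
#'
#' @param seed integer seed; every derived dataset is a deterministic
#'   function of it.
#' @param n_loci,n_decoys numbers of planted loci and decoy cluster
#'   pairs (defaults 12 and 8).
#' @param arm_len mature arm length in nt (default 21).
#' @param canonical_fraction fraction of arm reads with exactly
#'   canonical ends (default 0.7).
#' @param offset_5p_probs,offset_3p_probs named probability vectors for
#'   the 5' start and 3' end offsets of non-canonical reads; support
#'   must stay inside the \[-3,+5\] isomiR window. The 5' default is
#'   concentrated on 0 - plant Dicer cuts the 5' end precisely, so
#'   most isomiRs are 3' variants.
#' @param nta_rate_a,nta_rate_u per-read probabilities of a 1-nt
#'   non-templated adenylation / uridylation (defaults 0.04 and 0.06).
#' @param antisense_rate probability that a read is emitted from the
#'   opposite strand (default 0.05).
#' @param loop_read_rate expected loop-derived reads per arm read
#'   (default 0.02); loop fragments are 16-19 nt.
#' @param n_background distinct unmappable background sequences per
#'   library (default 200), emulating the non-miRNA bulk of a small-RNA
#'   library; their summed count is Poisson around `background_total`.
#' @param background_total expected total background read count per
#'   library (default 50000). Real libraries are dominated by other
#'   small RNAs, which keeps RPM denominators comparable between
#'   conditions; this reproduces that regime.
#' @param degradome_canonical_fraction fraction of degradome tags whose
#'   5' end sits at the transcript nt paired with miRNA position 10
#'   (default 0.8); the rest are uniform background.
#' @param n_tags_per_site degradome tags per cleaved site (default 400).
#' @param loci optional replacement for the per-locus design tibble
#'   (columns `locus`, `strand`, `mean_a`, `mean_b`, `arm_ratio_3p5p`,
#'   `shares_mature_with`).
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_loci = 12, n_decoys = 8, arm_len = 21,
                       canonical_fraction = 0.7,
                       offset_5p_probs = c("-2" = 0.06, "-1" = 0.12,
                                           "0" = 0.6, "1" = 0.12,
                                           "2" = 0.06, "3" = 0.04),
                       offset_3p_probs = c("-2" = 0.2, "-1" = 0.4,
                                           "1" = 0.3, "2" = 0.1),
                       nta_rate_a = 0.04, nta_rate_u = 0.06,
                       antisense_rate = 0.05, loop_read_rate = 0.02,
                       n_background = 200, background_total = 50000,
                       degradome_canonical_fraction = 0.8,
                       n_tags_per_site = 400,
                       loci = NULL) {
  stopifnot(canonical_fraction >= 0, canonical_fraction <= 1,
            nta_rate_a >= 0, nta_rate_u >= 0, nta_rate_a + nta_rate_u <= 1,
            antisense_rate >= 0, antisense_rate <= 1)
  offset_5p_probs <- offset_5p_probs / sum(offset_5p_probs)
  offset_3p_probs <- offset_3p_probs / sum(offset_3p_probs)
  if (is.null(loci)) {
    loci <- default_locus_design(n_loci)
  }
  structure(list(
    seed = seed, n_loci = nrow(loci), n_decoys = n_decoys,
    arm_len = arm_len, canonical_fraction = canonical_fraction,
    offset_5p_probs = offset_5p_probs, offset_3p_probs = offset_3p_probs,
    nta_rate_a = nta_rate_a, nta_rate_u = nta_rate_u,
    antisense_rate = antisense_rate, loop_read_rate = loop_read_rate,
    n_background = n_background, background_total = background_total,
    degradome_canonical_fraction = degradome_canonical_fraction,
    n_tags_per_site = n_tags_per_site,
    loci = loci), class = "sim_config")
}

# the study-like per-locus design: expression means per condition,
# 3p/5p arm skew, strand, and which loci share a mature sequence
default_locus_design <- function(n_loci = 12) {
  d <- tibble::tibble(
    locus = 1:12,
    strand = c("+", "+", "+", "+", "+", "-", "+", "+", "-", "+", "+", "-"),
    mean_a = c(600, 145, 120, 120, 24, 300, 90, 250, 180, 60, 400, 100),
    mean_b = c(100, 0, 40, 40, 8, 50, 45, 3, 30, 20, 80, 25),
    arm_ratio_3p5p = c(41, 29, 10, 10, 0.2, 29, 15, 20, 10, 5, 30, 8),
    shares_mature_with = c(NA, NA, NA, 3L, rep(NA, 8))
  )
  if (n_loci > 12) abort("default design supports up to 12 loci")
  d[seq_len(n_loci), ]
}

# design one hairpin whose candidate (cluster-span) region folds below
# the acceptance threshold; retried until the built-in folder agrees
design_hairpin <- function(arm_len, mfe_max = -38, max_tries = 50) {
  for (i in seq_len(max_tries)) {
    loop_len <- sample(18:24, 1)
    arm <- random_dna(arm_len, gc = 0.6)
    ext5 <- random_dna(2, gc = 0.5)
    ext3 <- random_dna(2, gc = 0.5)
    # A/C-only loop: cannot pair with itself, so the terminal loop
    # stays single-stranded and can shed 16-19 nt loop reads
    loop_seq <- paste(sample(c("A", "C"), loop_len, replace = TRUE,
                             prob = c(0.6, 0.4)), collapse = "")
    # up to two designed G:U wobbles in the 3p arm: real duplexes are
    # imperfect, and this breaks the strand ambiguity a perfect
    # inverted repeat would create for read mapping
    arm3 <- strsplit(revcomp(arm), "")[[1]]
    elig <- which(arm3 %in% c("C", "A"))
    elig <- elig[elig > 2 & elig < arm_len - 1]
    for (p in sample(elig, min(2, length(elig)))) {
      arm3[p] <- if (arm3[p] == "C") "T" else "G"   # G:T / T:G wobble
    }
    full <- paste0(ext5, arm, loop_seq, paste(arm3, collapse = ""), ext3)
    # the discovered candidate spans cluster A start .. cluster B end
    cand <- substr(full, 3, nchar(full))
    fold <- fold_mfe(cand)
    anat <- annotate_hairpin(fold)
    if (fold$mfe <= mfe_max && !anat$multiloop && !anat$unfolded &&
        anat$loop[1] >= arm_len - 2 &&
        anat$loop[2] <= arm_len + loop_len + 2 &&
        anat$loop[2] - anat$loop[1] >= 16) {
      return(list(full = full, loop_len = loop_len, arm = arm,
                  mfe = fold$mfe))
    }
  }
  abort("failed to design a hairpin below the MFE threshold")
}

#' Generate the synthetic genome and its ground-truth manifest
#'
#' Plants `n_loci` pre-miRNA hairpins (arm + loop + reverse-complement
#' arm, with 2-nt genomic extensions so mature duplexes carry the
#' canonical 2-nt 3' overhangs) and `n_decoys` AT-rich non-folding
#' decoy regions into random background sequence. Loci designated in
#' the design as sharing a mature sequence are planted as two copies
#' of the same hairpin ~2000 nt apart. The manifest records every
#' planted coordinate, arm and canonical mature, and is sufficient to
#' compute every downstream expectation.
#'
#' @param config a [sim_config()].
#' @return a `sim_data` list: `genome` (tibble `name`, `seq`),
#'   `manifest` (per-locus tibble), `decoys` (decoy cluster
#'   coordinates), `mature_refs` (a miRBase-like reference set: each
#'   distinct planted guide with one substitution), `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  arm_len <- config$arm_len
  design <- config$loci

  hairpins <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    share <- design$shares_mature_with[i]
    hairpins[[i]] <- if (!is.na(share)) hairpins[[share]]
    else design_hairpin(arm_len)
  }

  spacer <- function(n) random_dna(n, gc = 0.45)
  pieces <- character(0)
  cursor <- 0L
  manifest <- list()
  append_piece <- function(s) {
    pieces[[length(pieces) + 1]] <<- s
    cursor <<- cursor + nchar(s)
  }

  for (i in seq_len(nrow(design))) {
    share <- design$shares_mature_with[i]
    gap <- if (!is.na(share)) {
      # clustered gene pair: ~2000 nt between the two copies
      2000L - nchar(hairpins[[i]]$full)
    } else 400L + sample(0:200, 1)
    append_piece(spacer(gap))
    hp <- hairpins[[i]]
    L <- nchar(hp$full)
    strand <- design$strand[i]
    gseg <- if (strand == "+") hp$full else revcomp(hp$full)
    g0 <- cursor                        # genomic start of the planted segment
    append_piece(gseg)
    # precursor coordinates of the planted anatomy (hp$full orientation)
    m5 <- c(2L, 2L + arm_len)
    m3 <- c(L - arm_len - 2L + 2L, L)   # ends 2 nt past the paired arm
    loop <- c(2L + arm_len, 2L + arm_len + hp$loop_len)
    p2g <- function(iv) {
      if (strand == "+") c(g0 + iv[1], g0 + iv[2])
      else c(g0 + L - iv[2], g0 + L - iv[1])
    }
    g5 <- p2g(m5); g3 <- p2g(m3); gl <- p2g(loop)
    manifest[[i]] <- tibble::tibble(
      locus = design$locus[i], chrom = "chr1", strand = strand,
      start = g0, end = g0 + L,
      mature_5p_seq = substr(hp$full, m5[1] + 1, m5[2]),
      mature_3p_seq = substr(hp$full, m3[1] + 1, m3[2]),
      mature_5p_start = g5[1], mature_5p_end = g5[2],
      mature_3p_start = g3[1], mature_3p_end = g3[2],
      loop_start = gl[1], loop_end = gl[2],
      prec_seq = hp$full, designed_mfe = hp$mfe,
      mean_a = design$mean_a[i], mean_b = design$mean_b[i],
      arm_ratio_3p5p = design$arm_ratio_3p5p[i])
  }

  decoys <- list()
  for (d in seq_len(config$n_decoys)) {
    append_piece(spacer(400L + sample(0:200, 1)))
    # AT-rich region that does not fold; two read sites < 150 nt apart
    region <- random_dna(arm_len + 60 + arm_len, gc = 0.15)
    g0 <- cursor
    append_piece(region)
    decoys[[d]] <- tibble::tibble(
      decoy = d, chrom = "chr1", strand = "+",
      site_a_start = g0, site_a_end = g0 + arm_len,
      site_b_start = g0 + arm_len + 60L,
      site_b_end = g0 + 2L * arm_len + 60L)
  }
  append_piece(spacer(400L))

  manifest <- dplyr::bind_rows(manifest)
  genome <- tibble::tibble(name = "chr1", seq = paste(pieces, collapse = ""))

  # miRBase-like reference set: one entry per distinct guide sequence,
  # carrying a single substitution like a homolog from another species
  mats <- unique(manifest$mature_3p_seq)
  refs <- purrr::imap(mats, function(m, i) {
    pos <- sample(15:nchar(m), 1)       # outside the 5' seed region
    ch <- strsplit(m, "")[[1]]
    ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    tibble::tibble(name = paste0("ref-mir", i),
                   seq = paste(ch, collapse = ""))
  }) |> dplyr::bind_rows()

  structure(list(genome = genome, manifest = manifest,
                 decoys = dplyr::bind_rows(decoys),
                 mature_refs = refs, config = config),
            class = "sim_data")
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> seed %d: %d nt genome, %d planted loci, %d decoys\n",
              x$config$seed, nchar(x$genome$seq[1]),
              nrow(x$manifest), nrow(x$decoys)))
  invisible(x)
}

# sample one offset from a named probability vector
sample_offset <- function(probs) {
  as.integer(sample(names(probs), 1, prob = probs))
}

#' Generate one condition's collapsed small-RNA library
#'
#' Per locus, the total read count is Poisson around the condition
#' mean and split between arms by the configured 3p/5p ratio. Each
#' read draws canonical ends with probability `canonical_fraction` or
#' offsets from the configured distributions (inside the \[-3,+5\]
#' window); non-templated 1-nt A/U tails, antisense placements and
#' 16-19 nt loop fragments are emitted at their configured rates, and
#' decoy sites emit reads with fluctuating 5' ends over non-folding
#' sequence. Identical sequences collapse into one read with summed
#' count.
#'
#' @param sim a [simulate_genome()] result.
#' @param condition `"A"` or `"B"`.
#' @return a list: `reads` (collapsed tibble `read_id`, `seq`,
#'   `count`), `emitted` (ground-truth per-locus event tallies:
#'   sense/antisense, per-arm, canonical, NTA and loop counts),
#'   `total_input_reads`.
#' @export
simulate_reads <- function(sim, condition = c("A", "B")) {
  condition <- match.arg(condition)
  config <- sim$config
  set.seed(config$seed * 131L + ifelse(condition == "A", 7L, 8L))
  man <- sim$manifest

  events <- list()
  tallies <- list()
  for (i in seq_len(nrow(man))) {
    l <- man[i, ]
    mean_cnt <- if (condition == "A") l$mean_a else l$mean_b
    n_tot <- if (mean_cnt > 0) rpois(1, mean_cnt) else 0L
    tally <- list(locus = l$locus, condition = condition, n_total = n_tot,
                  n_3p = 0L, n_5p = 0L, n_canonical = 0L, n_nta_a = 0L,
                  n_nta_u = 0L, n_antisense = 0L, n_loop = 0L)
    if (n_tot > 0) {
      p3 <- l$arm_ratio_3p5p / (1 + l$arm_ratio_3p5p)
      P <- l$prec_seq
      Lp <- nchar(P)
      # manifest intervals in precursor coordinates
      g2p <- function(gs, ge) {
        if (l$strand == "+") c(gs - l$start, ge - l$start)
        else c(l$end - ge, l$end - gs)
      }
      m5 <- g2p(l$mature_5p_start, l$mature_5p_end)
      m3 <- g2p(l$mature_3p_start, l$mature_3p_end)
      for (r in seq_len(n_tot)) {
        is3p <- runif(1) < p3
        m <- if (is3p) m3 else m5
        if (is3p) tally$n_3p <- tally$n_3p + 1L
        else tally$n_5p <- tally$n_5p + 1L
        if (runif(1) < config$canonical_fraction) {
          s <- m[1]; e <- m[2]
          tally$n_canonical <- tally$n_canonical + 1L
        } else {
          repeat {
            s <- m[1] + sample_offset(config$offset_5p_probs)
            e <- m[2] + sample_offset(config$offset_3p_probs)
            if (s >= m[1] - 3 && e <= m[2] + 5 && e - s >= 16 &&
                s >= 0 && e <= Lp) break
          }
        }
        seq <- substr(P, s + 1, e)
        if (runif(1) < config$antisense_rate) {
          # antisense reads are genome-templated on the other strand;
          # they carry no non-templated tail
          events[[length(events) + 1]] <- revcomp(seq)
          tally$n_antisense <- tally$n_antisense + 1L
          next
        }
        # non-templated 1-nt tail; shift the templated end inward when
        # the sampled letter happens to be templated at that position
        u <- runif(1)
        tail_letter <- if (u < config$nta_rate_a) "A"
        else if (u < config$nta_rate_a + config$nta_rate_u) "T"
        else NA_character_
        if (!is.na(tail_letter)) {
          for (shift in 0:2) {
            e2 <- e - shift
            nxt <- if (e2 < Lp) substr(P, e2 + 1, e2 + 1) else ""
            if (nxt != tail_letter && e2 - s >= 16) {
              seq <- paste0(substr(P, s + 1, e2), tail_letter)
              if (tail_letter == "A") tally$n_nta_a <- tally$n_nta_a + 1L
              else tally$n_nta_u <- tally$n_nta_u + 1L
              break
            }
          }
        }
        events[[length(events) + 1]] <- seq
      }
      # loop-derived fragments, 16-19 nt inside the terminal loop
      lp <- g2p(l$loop_start, l$loop_end)
      loop_len <- lp[2] - lp[1]
      n_loop <- rpois(1, n_tot * config$loop_read_rate)
      for (r in seq_len(n_loop)) {
        flen <- sample(16:min(19, loop_len), 1)
        fs <- lp[1] + sample(0:(loop_len - flen), 1)
        events[[length(events) + 1]] <- substr(P, fs + 1, fs + flen)
        tally$n_loop <- tally$n_loop + 1L
      }
    }
    tallies[[i]] <- tibble::as_tibble(tally)
  }

  # decoy sites: abundant reads with fluctuating 5' ends
  gseq <- sim$genome$seq[1]
  for (d in seq_len(nrow(sim$decoys))) {
    dk <- sim$decoys[d, ]
    for (site in c("a", "b")) {
      s0 <- dk[[paste0("site_", site, "_start")]]
      n <- rpois(1, 30)
      for (r in seq_len(n)) {
        s <- s0 + sample(0:5, 1)
        events[[length(events) + 1]] <- substr(gseq, s + 1, s + config$arm_len)
      }
    }
  }

  # unmappable background: the non-miRNA bulk of the library, so RPM
  # denominators reflect realistic input totals
  n_bg <- config$n_background
  bg <- tibble::tibble(
    seq = vapply(seq_len(n_bg), function(i) random_dna(sample(20:24, 1), 0.5),
                 character(1)),
    count = rpois(n_bg, config$background_total / max(n_bg, 1)))
  bg <- bg[bg$count > 0, ]

  reads <- tibble::tibble(seq = unlist(events), count = 1L) |>
    dplyr::bind_rows(bg) |>
    dplyr::group_by(.data$seq) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq) |>
    dplyr::mutate(read_id = paste0("sim", dplyr::row_number()),
                  count = as.integer(.data$count)) |>
    dplyr::select("read_id", "seq", "count")

  list(reads = reads, emitted = dplyr::bind_rows(tallies),
       total_input_reads = length(events) + sum(bg$count))
}

#' Generate transcripts, planted target sites and degradome tags
#'
#' Builds one transcript per selected guide miRNA with a perfectly
#' complementary site, plus one multi-site transcript carrying five
#' sites of the first guide of which two are cleaved - mirroring a
#' PHO2-like 5' UTR. Tags are `tag_len`-nt transcript suffixes:
#' `degradome_canonical_fraction` of each cleaved site's tags start at
#' the transcript nt paired with miRNA position 10, the rest start
#' uniformly across the transcript.
#'
#' @param sim a [simulate_genome()] result.
#' @param n_mirnas how many distinct guides get single-site transcripts
#'   (default 3).
#' @return a list: `transcripts` (tibble `name`, `seq`), `sites`
#'   (planted site manifest with `cleaved` flag), `tags` (collapsed
#'   tag tibble), `mirnas` (tibble of the guides used).
#' @export
simulate_degradome <- function(sim, n_mirnas = 3) {
  config <- sim$config
  set.seed(config$seed * 131L + 9L)
  tag_len <- 20L
  mats <- unique(sim$manifest$mature_3p_seq)
  mirnas <- tibble::tibble(name = paste0("mir", seq_len(n_mirnas)),
                           seq = mats[seq_len(n_mirnas)])

  transcripts <- list(); sites <- list()
  plant <- function(tx_name, mir_name, mir_seq, positions, cleaved) {
    site <- revcomp(mir_seq)
    m <- nchar(site)
    tx <- random_dna(600, gc = 0.45)
    for (k in seq_along(positions)) {
      p <- positions[k]
      tx <- paste0(substr(tx, 1, p), site, substr(tx, p + m + 1, nchar(tx)))
      sites[[length(sites) + 1]] <<- tibble::tibble(
        transcript = tx_name, mirna_id = mir_name,
        start = p, end = p + m, cleaved = cleaved[k])
    }
    transcripts[[length(transcripts) + 1]] <<- tibble::tibble(
      name = tx_name, seq = tx)
  }
  for (i in seq_len(n_mirnas)) {
    plant(paste0("tx", i), mirnas$name[i], mirnas$seq[i],
          positions = 300, cleaved = TRUE)
  }
  # PHO2-like: five sites, only sites 2 and 5 cleaved
  plant("tx_multi", mirnas$name[1], mirnas$seq[1],
        positions = c(60, 160, 260, 360, 460),
        cleaved = c(FALSE, TRUE, FALSE, FALSE, TRUE))
  transcripts <- dplyr::bind_rows(transcripts)
  sites <- dplyr::bind_rows(sites)

  tags <- list()
  for (i in seq_len(nrow(sites))) {
    s <- sites[i, ]
    if (!s$cleaved) next
    tx <- transcripts$seq[transcripts$name == s$transcript]
    n_can <- rbinom(1, config$n_tags_per_site,
                    config$degradome_canonical_fraction)
    # 5' end at the transcript nt paired with miRNA position 10
    canon_pos <- s$end - 10L
    bg_pos <- sample(0:(nchar(tx) - tag_len), config$n_tags_per_site - n_can,
                     replace = TRUE)
    pos <- c(rep(canon_pos, n_can), bg_pos)
    tags[[length(tags) + 1]] <- tibble::tibble(
      seq = substring(tx, pos + 1, pos + tag_len))
  }
  tags <- dplyr::bind_rows(tags) |>
    dplyr::count(.data$seq, name = "count") |>
    dplyr::arrange(dplyr::desc(.data$count), .data$seq) |>
    dplyr::mutate(read_id = paste0("tag", dplyr::row_number()),
                  count = as.integer(.data$count)) |>
    dplyr::select("read_id", "seq", "count")

  list(transcripts = transcripts, sites = sites, tags = tags,
       mirnas = mirnas)
}

#' Run the full synthetic benchmark generator
#'
#' @param seed integer seed.
#' @param config optional [sim_config()]; built from `seed` when
#'   absent.
#' @return a list bundling [simulate_genome()], both
#'   [simulate_reads()] libraries (`reads_a`, `reads_b`) and the
#'   [simulate_degradome()] set.
#' @export
simulate_benchmark <- function(seed = 1, config = sim_config(seed)) {
  sim <- simulate_genome(config)
  list(sim = sim,
       reads_a = simulate_reads(sim, "A"),
       reads_b = simulate_reads(sim, "B"),
       degradome = simulate_degradome(sim))
}
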