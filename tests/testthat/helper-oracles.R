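# independent brute-force oracles; deliberately written without reusing
# any package internals beyond revcomp()

# --- naive all-positions exact mapper -------------------------------------
naive_map <- function(read, genome_tbl) {
  out <- list()
  for (r in seq_len(nrow(genome_tbl))) {
    g <- genome_tbl$seq[r]; nm <- genome_tbl$name[r]
    n <- nchar(read); L <- nchar(g)
    if (L < n) next
    for (s in 0:(L - n)) {
      win <- substr(g, s + 1, s + n)
      if (win == read) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = nm, start = s, end = s + n, strand = "+")
      }
      if (win == revcomp(read)) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = nm, start = s, end = s + n, strand = "-")
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character()))
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(chrom, start, strand)
}

# --- straight-line re-simulation of the greedy clustering rule ------------
naive_cluster <- function(aln, flank_up = 3, flank_down = 5) {
  ord <- order(-aln$count, aln$chrom, aln$start, aln$strand, aln$seq)
  aln <- aln[ord, ]
  clusters <- list()
  assign <- integer(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      cl <- clusters[[ci]]
      if (cl$chrom == aln$chrom[i] && cl$strand == aln$strand[i] &&
          aln$start[i] >= cl$start - flank_up &&
          aln$end[i] <= cl$end + flank_down) {
        assign[i] <- ci; placed <- TRUE; break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1]] <- list(
        chrom = aln$chrom[i], strand = aln$strand[i],
        start = aln$start[i], end = aln$end[i])
      assign[i] <- length(clusters)
    }
  }
  tibble::tibble(read_id = aln$read_id, cluster = assign,
                 c_start = vapply(clusters, `[[`, 0, "start")[assign],
                 c_end = vapply(clusters, `[[`, 0, "end")[assign])
}

# --- exhaustive secondary-structure enumeration ---------------------------
# all pseudoknot-free pair sets on n bases with minimum hairpin loop 3,
# as a list of 2-column matrices (0-based pair indices)
enumerate_skeletons <- function(n, min_loop = 3) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i + 1 <= 0) return(list(matrix(0L, 0, 2)))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- lapply(rec(i + 1, j), identity)           # i unpaired
    for (k in (i + min_loop + 1):j) {
      if (k > j) break
      left <- rec(i + 1, k - 1)
      right <- rec(k + 1, j)
      for (a in left) for (b in right) {
        res[[length(res) + 1]] <- rbind(c(i, k), a, b)
      }
    }
    memo[[key]] <- res
    res
  }
  if (n < min_loop + 2) return(list(matrix(0L, 0, 2)))
  rec(0L, n - 1L)
}

# loop decomposition of one skeleton, independent of sequence:
# for each pair, its directly nested child pairs
skeleton_topology <- function(pairs) {
  if (nrow(pairs) == 0) return(list())
  apply(pairs, 1, function(p) {
    i <- p[1]; j <- p[2]
    inner <- pairs[pairs[, 1] > i & pairs[, 2] < j, , drop = FALSE]
    if (nrow(inner) > 0) {
      # children: inner pairs not nested in another inner pair
      keep <- vapply(seq_len(nrow(inner)), function(q) {
        !any(inner[, 1] < inner[q, 1] & inner[, 2] > inner[q, 2])
      }, logical(1))
      inner <- inner[keep, , drop = FALSE]
    }
    list(i = i, j = j, children = inner)
  }, simplify = FALSE)
}

# energy of one skeleton for one sequence under the package's parameter
# tables, by direct loop-decomposition bookkeeping (no DP)
oracle_pair_type <- function(a, b) {
  key <- paste0(a, b)
  idx <- c(AT = 1, CG = 2, GC = 3, GT = 4, TA = 5, TG = 6)[key]
  if (is.na(idx)) NA_integer_ else unname(idx)
}

oracle_energy <- function(seq, pairs, topo, par,
                          ml_init = 3.4, ml_branch = 0.4) {
  ch <- strsplit(seq, "")[[1]]
  if (nrow(pairs) == 0) return(0)
  for (q in seq_len(nrow(pairs))) {
    if (is.na(oracle_pair_type(ch[pairs[q, 1] + 1], ch[pairs[q, 2] + 1]))) {
      return(Inf)
    }
  }
  e <- 0
  for (node in topo) {
    i <- node$i; j <- node$j; kids <- node$children
    if (nrow(kids) == 0) {
      e <- e + par$hairpin[j - i - 1]
    } else if (nrow(kids) == 1) {
      k <- kids[1, 1]; l <- kids[1, 2]
      n1 <- k - i - 1; n2 <- j - l - 1
      if (n1 == 0 && n2 == 0) {
        e <- e + par$stack[oracle_pair_type(ch[i + 1], ch[j + 1]),
                           oracle_pair_type(ch[k + 1], ch[l + 1])]
      } else if (n1 == 0 || n2 == 0) {
        e <- e + par$bulge[n1 + n2]
      } else {
        e <- e + par$internal[n1 + n2]
      }
    } else {
      e <- e + ml_init + ml_branch * (1 + nrow(kids))
    }
  }
  if (is.na(e)) Inf else e
}

# --- exhaustive isomiR decomposition --------------------------------------
# every (start, templated_end, tail) split; longest templated part wins,
# ties resolved towards the anchor nearest the canonical start
oracle_isomir <- function(seq, canonical, precursor, max_tail = 3,
                          window_up = 3, window_down = 5) {
  n <- nchar(seq); plen <- nchar(precursor)
  best <- NULL
  for (s in 0:(plen - 1)) {
    if (s < canonical[1] - window_up || s > canonical[2] - 1) next
    for (tl in seq(n, max(1, n - max_tail))) {
      if (s + tl > plen) next
      if (s + n > canonical[2] + window_down) next
      tmpl <- substr(precursor, s + 1, s + tl)
      mm <- which(strsplit(tmpl, "")[[1]] != strsplit(substr(seq, 1, tl),
                                                      "")[[1]])
      tail <- if (tl < n) substr(seq, tl + 1, n) else ""
      max_mm <- if (tail == "") 1 else 0
      if (length(mm) > max_mm) next
      # a terminal mismatch is a non-templated addition, not a substitution
      if (tail == "" && any(mm == tl)) next
      if (tail != "") {
        tch <- strsplit(tail, "")[[1]]
        tpos <- s + tl + seq_along(tch)
        pch <- strsplit(precursor, "")[[1]]
        if (any(tpos <= plen & pch[pmin(tpos, plen)] == tch)) next
      }
      cand <- list(s = s, tl = tl, tail = tail, mm = length(mm))
      if (is.null(best) || cand$tl > best$tl ||
          (cand$tl == best$tl &&
           abs(cand$s - canonical[1]) < abs(best$s - canonical[1]))) {
        best <- cand
      }
    }
  }
  best
}

# --- brute-force target alignment -----------------------------------------
oracle_target_penalty <- function(mirna, window) {
  n <- nchar(mirna); w <- nchar(window)
  mir <- strsplit(mirna, "")[[1]]
  wrev <- rev(strsplit(window, "")[[1]])
  colpen <- function(mb, tb, pos) {
    base <- if ((mb == "A" && tb == "T") || (mb == "T" && tb == "A") ||
                (mb == "G" && tb == "C") || (mb == "C" && tb == "G")) 0
    else if ((mb == "G" && tb == "T") || (mb == "T" && tb == "G")) 0.5
    else 1
    base * (if (pos >= 2 && pos <= 13) 2 else 1)
  }
  gappen <- function(pos) 2 * (if (pos >= 2 && pos <= 13) 2 else 1)
  if (w == n) {
    return(sum(mapply(colpen, mir, wrev, seq_len(n))))
  }
  best <- Inf
  if (w == n - 1) {
    for (g in seq_len(n)) {
      pen <- gappen(g)
      wi <- 1
      for (p in seq_len(n)) {
        if (p == g) next
        pen <- pen + colpen(mir[p], wrev[wi], p)
        wi <- wi + 1
      }
      best <- min(best, pen)
    }
  } else {
    for (g in 0:n) {
      pen <- gappen(max(g, 1))
      wi <- 1
      for (p in seq_len(n)) {
        if (wi == g + 1) wi <- wi + 1       # skip the bulged window base
        pen <- pen + colpen(mir[p], wrev[wi], p)
        wi <- wi + 1
      }
      best <- min(best, pen)
    }
  }
  best
}
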