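#' Nearest-neighbour folding parameters
#'
#' Loads the parameter tables shipped with the package: stacking free
#' energies for the 36 ordered Watson-Crick/G:U pair stacks and
#' length-dependent hairpin, bulge and internal-loop penalties
#' (tabulated to 30 nt; larger loops are extrapolated logarithmically).
#' Multiloops carry an affine cost (`ml_init` per multiloop plus
#' `ml_branch` per helix including the closing one; unpaired multiloop
#' bases are free). All energies are kcal/mol at 37 degrees C.
#'
#' @return a list with elements `stack` (6x6 matrix, pairs in
#'   alphabetical order AT, CG, GC, GT, TA, TG), `hairpin`, `bulge`,
#'   `internal` (numeric length-30 vectors indexed by loop size),
#'   `ml_init`, `ml_branch`, `ml_unpaired`, `max_interior`.
#' @export
fold_params <- function() {
  st <- readr::read_tsv(system.file("extdata", "nn_stack.tsv",
                                    package = "mirloci"),
                        show_col_types = FALSE)
  lp <- readr::read_tsv(system.file("extdata", "nn_loops.tsv",
                                    package = "mirloci"),
                        show_col_types = FALSE)
  pairs <- c("AT", "CG", "GC", "GT", "TA", "TG")
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(match(st$outer, pairs), match(st$inner, pairs))] <- st$dG
  list(stack = stack, hairpin = lp$hairpin, bulge = lp$bulge,
       internal = lp$internal,
       ml_init = 3.4, ml_branch = 0.4, ml_unpaired = 0.0,
       max_interior = 30L)
}

#' The built-in folding engine
#'
#' Returns the default engine function used by [fold_mfe()]: a dynamic
#' program over the nearest-neighbour model of [fold_params()] that
#' computes the pseudoknot-free minimum-free-energy structure
#' (minimum hairpin loop 3, G:U pairs allowed, interior loops capped at
#' 30 unpaired nt, no dangles). Deterministic for fixed input.
#'
#' An engine is any `function(seq)` returning
#' `list(structure = <dot-bracket>, mfe = <kcal/mol>)`; an external
#' thermodynamic folder can be substituted through the `engine`
#' argument of [fold_mfe()].
#'
#' @param params a parameter list as returned by [fold_params()].
#' @return an engine function.
#' @export
fold_engine_nn <- function(params = fold_params()) {
  force(params)
  function(seq) {
    .fold_engine_cpp(seq, params$stack, params$hairpin, params$bulge,
                     params$internal, params$ml_init, params$ml_branch,
                     params$ml_unpaired, params$max_interior)
  }
}

# engine cached per session so fold_mfe() calls are cheap
the <- new.env(parent = emptyenv())
default_engine <- function() {
  if (is.null(the$engine)) the$engine <- fold_engine_nn()
  the$engine
}

#' Fold a sequence into its minimum-free-energy structure
#'
#' @param seq a DNA/RNA sequence (U is converted to T); non-ACGT
#'   characters are unpairable, and more than 5 percent of them is an
#'   error.
#' @param engine a folding engine function (see [fold_engine_nn()]);
#'   `NULL` uses the built-in nearest-neighbour engine.
#' @return a `fold_result`: list with `seq`, `structure` (dot-bracket),
#'   `mfe` (kcal/mol, never positive).
#' @examples
#' fold_mfe("GGGGAAAACCCC")
#' @export
fold_mfe <- function(seq, engine = NULL) {
  seq <- normalize_dna(seq)
  frac_bad <- mean(strsplit(seq, "")[[1]] %in% c("A", "C", "G", "T") == FALSE)
  if (frac_bad > 0.05) {
    abort(sprintf("sequence has %.0f%% non-ACGT characters (max 5%%)",
                  100 * frac_bad))
  }
  engine <- engine %||% default_engine()
  res <- engine(seq)
  stopifnot(nchar(res$structure) == nchar(seq), res$mfe <= 0)
  structure(list(seq = seq, structure = res$structure, mfe = res$mfe),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$seq, "\n", x$structure, "\n", sep = "")
  cat(sprintf("mfe = %.2f kcal/mol\n", x$mfe))
  invisible(x)
}

# pair table from dot-bracket: 0-based partner or NA
pair_table <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  partner <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) abort("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j - 1L
      partner[j] <- i - 1L
    }
  }
  if (length(stack) > 0) abort("unbalanced dot-bracket string")
  partner
}

#' Annotate hairpin anatomy from a fold
#'
#' Locates the terminal loop (the maximal unpaired run inside the
#' innermost pair) and the two stems flanking it. A structure with more
#' than one hairpin loop is flagged `multiloop = TRUE` and downstream
#' candidates fail the stem filter; an unpaired structure is flagged
#' `unfolded`.
#'
#' @param fold a [fold_mfe()] result.
#' @return a list with 0-based half-open intervals `stem5p`, `stem3p`,
#'   `loop`, plus `n_pairs`, `multiloop`, `unfolded`.
#' @export
annotate_hairpin <- function(fold) {
  partner <- pair_table(fold$structure)
  paired <- which(!is.na(partner)) - 1L             # 0-based
  n_pairs <- length(paired) %/% 2L
  if (n_pairs == 0) {
    return(list(stem5p = NULL, stem3p = NULL, loop = NULL,
                n_pairs = 0L, multiloop = FALSE, unfolded = TRUE))
  }
  # hairpin loops = pairs with no paired base strictly inside
  ch <- strsplit(fold$structure, "")[[1]]
  opens <- which(ch == "(") - 1L
  is_hp_closing <- vapply(opens, function(i) {
    j <- partner[i + 1L]
    j - i >= 2 && all(is.na(partner[(i + 2L):j]))
  }, logical(1))
  n_loops <- sum(is_hp_closing)
  if (n_loops != 1L) {
    return(list(stem5p = NULL, stem3p = NULL, loop = NULL,
                n_pairs = n_pairs, multiloop = TRUE, unfolded = FALSE))
  }
  i_in <- opens[is_hp_closing]                       # innermost 5' pair
  j_in <- partner[i_in + 1L]
  list(stem5p = c(min(paired), i_in + 1L),
       stem3p = c(j_in, max(paired) + 1L),
       loop = c(i_in + 1L, j_in),
       n_pairs = n_pairs, multiloop = FALSE, unfolded = FALSE)
}

#' 3' overhangs of the miRNA/miRNA* duplex
#'
#' Projects each arm's 5' end across the folded helix and measures how
#' far the opposite arm's 3' end extends past it. Canonical
#' plant-Dicer processing leaves a 2-nt 3' overhang on both strands.
#'
#' @param fold a [fold_mfe()] result for the precursor.
#' @param mature5p,mature3p 0-based half-open intervals of the two arms
#'   on the precursor.
#' @return a list with `overhang_5p`, `overhang_3p` (3' overhang of the
#'   5p and 3p strands respectively) and `canonical` (`TRUE` iff both
#'   are exactly 2).
#' @export
check_duplex_overhang <- function(fold, mature5p, mature3p) {
  anat <- annotate_hairpin(fold)
  if (anat$unfolded || anat$multiloop) {
    abort("duplex overhangs require a single-hairpin fold")
  }
  overlaps <- function(a, b) a[1] < b[2] && b[1] < a[2]
  if (overlaps(mature5p, anat$loop) || overlaps(mature3p, anat$loop)) {
    abort("a mature arm overlaps the terminal loop; no duplex is formed")
  }
  partner <- pair_table(fold$structure)
  project_5p_end <- function(arm) {
    # partner of the arm's 5'-most base, projected across any bulge
    i <- arm[1]
    while (i < arm[2] && is.na(partner[i + 1L])) i <- i + 1L
    if (i >= arm[2]) return(NA_integer_)
    partner[i + 1L] + (i - arm[1])
  }
  p5 <- project_5p_end(mature5p)                     # lands on 3p strand
  p3 <- project_5p_end(mature3p)                     # lands on 5p strand
  if (is.na(p5) || is.na(p3)) {
    abort("an arm has no paired base; duplex undefined")
  }
  overhang_3p <- (mature3p[2] - 1L) - p5
  overhang_5p <- (mature5p[2] - 1L) - p3
  list(overhang_5p = overhang_5p, overhang_3p = overhang_3p,
       canonical = overhang_5p == 2L && overhang_3p == 2L)
}
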