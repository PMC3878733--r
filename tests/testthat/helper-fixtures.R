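# shared fixtures, built once per test run

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# the study-like benchmark at seed 1 (12 planted loci, 8 decoys)
get_bench1 <- function() memo("bench1", simulate_benchmark(1))

pool_reads <- function(bench) {
  dplyr::bind_rows(bench$reads_a$reads, bench$reads_b$reads) |>
    dplyr::group_by(seq) |>
    dplyr::summarise(read_id = read_id[1], count = sum(count),
                     .groups = "drop") |>
    dplyr::select(read_id, seq, count)
}

# pooled-library discovery on the benchmark
get_disc1 <- function() memo("disc1", {
  bench <- get_bench1()
  discover_loci(pool_reads(bench), bench$sim$genome,
                mature_refs = bench$sim$mature_refs)
})

# a single toy locus with clean reads, for filter-level tests
make_toy_locus <- function(seed = 11, n_canonical = 40, offsets = NULL) {
  withr::with_seed(seed, {
    cfg <- sim_config(seed = seed, n_decoys = 0, n_background = 0,
                      canonical_fraction = 1, nta_rate_a = 0,
                      nta_rate_u = 0, antisense_rate = 0,
                      loop_read_rate = 0,
                      loci = tibble::tibble(
                        locus = 1L, strand = "+", mean_a = n_canonical,
                        mean_b = 0, arm_ratio_3p5p = 2,
                        shares_mature_with = NA_integer_))
    sim <- simulate_genome(cfg)
    reads <- simulate_reads(sim, "A")
    list(sim = sim, reads = reads$reads, emitted = reads$emitted)
  })
}
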