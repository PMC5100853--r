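# Shared fixtures, all built in code.  Expensive simulations are memoised in
# a session-local environment so multiple test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 11, n_mirnas_per_class = 2,
                         genome_length = 60000,
                         library_depth_mean = 4000, ...) {
  simulation_config(n_mirnas_per_class = n_mirnas_per_class,
                    genome_length = genome_length,
                    library_depth_mean = library_depth_mean,
                    seed = seed, ...)
}

# minimal FASTQ reader (independent of the package's parser)
parse_fastq_fixture <- function(path) {
  lines <- readLines(path)
  list(id = sub("^@", "", lines[c(TRUE, FALSE, FALSE, FALSE)]),
       seq = lines[c(FALSE, TRUE, FALSE, FALSE)],
       qual = lines[c(FALSE, FALSE, FALSE, TRUE)])
}

# one small simulated experiment (2 miRNAs/class, 18 libraries of 4k reads)
small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_experiment(
      small_config(), file.path(tempdir(), "mirmzt-small-sim"))
  }
  .fixture_env$sim
}

# the full-scale demo used by the end-to-end acceptance criterion
demo_run <- function() {
  if (is.null(.fixture_env$demo)) {
    .fixture_env$demo <- run_demo(file.path(tempdir(), "mirmzt-demo"),
                                  simulation_config(seed = 1))
  }
  .fixture_env$demo
}

# a hand-built micro reference bundle with exactly known coordinates:
# one 80-nt hairpin at 101..180 with its 22-nt mature arm at 116..137,
# a tRNA locus, a cis-NAT pair, one TE copy, an exon overlapping the hairpin
toy_bundle <- function(seed = 99) {
  g <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = ""))
  mk <- function(start, end, strand = "+", ...) {
    gr <- GenomicRanges::GRanges("toy", IRanges::IRanges(start, end),
                                 strand = strand)
    mc <- list(...)
    for (nm in names(mc)) S4Vectors::mcols(gr)[[nm]] <- mc[[nm]]
    gr
  }
  mirna <- data.frame(
    mirna_id = "mir-t1", hairpin_id = "hp-mir-t1", chrom = "toy",
    strand = "+", hp_start = 101L, hp_end = 180L,
    mat_start = 116L, mat_end = 137L, stringsAsFactors = FALSE)
  mirna$hairpin_seq <- substr(g, 101, 180)
  mirna$mature_seq <- substr(g, 116, 137)
  mirna$win_start <- 114L
  mirna$win_end <- 142L
  structure(list(
    chrom = "toy", genome = c(toy = g), mirna = mirna,
    layers = list(
      structural = mk(301, 400, name = "tRNA_01", subtype = "tRNA"),
      cisnat = mk(c(501, 601), c(700, 800), c("+", "-"),
                  name = c("cisnat_01_A", "cisnat_01_B"),
                  pair = c("cisnat_01", "cisnat_01")),
      te = mk(851, 950, name = "TE1_copy1", family = "TE1"),
      exon = mk(c(95, 1001), c(200, 1100),
                name = c("exon_mir_overlap", "exon_01")),
      intron = mk(1101, 1180, name = "intron_01")
    ),
    clusters = mk(820, 980, strand = "*", name = "cluster1"),
    te_consensus = c(TE1 = substr(g, 851, 950)),
    free = GenomicRanges::GRanges("toy", IRanges::IRanges(1, 90)),
    paths = NULL
  ), class = "ReferenceBundle")
}

# write a FASTQ from parallel id/seq/qual vectors
write_fastq <- function(path, seqs, quals = strrep("I", nchar(seqs)),
                        ids = sprintf("read%d", seq_along(seqs))) {
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# pick a base that differs from the genomic base at `pos` (for planting
# guaranteed-non-templated tails and mismatches)
mismatch_base <- function(genome, pos) {
  setdiff(c("A", "C", "G", "T"), substr(genome, pos, pos))[1]
}

# brute-force hypergeometric upper tail by direct enumeration (independent
# oracle for the Fisher overlap test)
enum_hyper_upper <- function(N, nA, nB, a) {
  j <- max(a, max(0, nA + nB - N)):min(nA, nB)
  sum(choose(nA, j) * choose(N - nA, nB - j)) / choose(N, nB)
}
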