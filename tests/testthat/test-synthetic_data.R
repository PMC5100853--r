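# synthetic_data module: config validation, reference generation, library
# simulation, and the generator's own invariants.

test_that("simulation_config validates its invariants", {
  expect_s3_class(small_config(), "simulation_config")
  expect_error(simulation_config(isoform_fractions = c(canonical = 0.8,
                                                       noncanonical = 0.1,
                                                       nta = 0.2)),
               "sum to 1")
  expect_error(simulation_config(nta_tail_freqs = c(A = 0.5, AA = 0.4)),
               "sum to 1")
  expect_error(simulation_config(nta_tail_freqs = c(AAAA = 1)), "1-3 nt")
  expect_error(simulation_config(n_te_families = 0))
})

test_that("generate_reference places features as declared", {
  cfg <- small_config()
  b <- generate_reference(cfg)
  m <- b$mirna
  expect_equal(nrow(m), 10)
  # every mature lies strictly inside its hairpin; windows contain matures
  expect_true(all(m$mat_start > m$hp_start & m$mat_end < m$hp_end))
  expect_true(all(m$win_start <= m$mat_start & m$win_end >= m$mat_end))
  expect_equal(m$win_start, m$mat_start - 2L)
  expect_equal(m$win_end, m$mat_end + 5L)
  # sequences are consistent with the genome
  g <- unname(b$genome)
  expect_equal(substring(g, m$mat_start, m$mat_end), m$mature_seq)
  expect_equal(substring(g, m$hp_start, m$hp_end), m$hairpin_seq)
  # cis-NAT pairs: 2 members each, overlapping, antisense
  cn <- b$layers$cisnat
  expect_equal(length(cn), 2L * cfg$n_cisnat_pairs)
  for (p in unique(S4Vectors::mcols(cn)$pair)) {
    pair <- cn[S4Vectors::mcols(cn)$pair == p]
    expect_setequal(as.character(GenomicRanges::strand(pair)), c("+", "-"))
    expect_gt(GenomicRanges::width(GenomicRanges::pintersect(
      pair[1], pair[2], ignore.strand = TRUE)), 0)
  }
  # TE copies are identical sequence (multi-mapping by construction)
  te <- b$layers$te
  fam <- S4Vectors::mcols(te)$family
  for (f in unique(fam)) {
    copies <- te[fam == f]
    seqs <- substring(g, GenomicRanges::start(copies),
                      GenomicRanges::end(copies))
    expect_equal(length(unique(seqs)), 1L)
    expect_equal(seqs[1], unname(b$te_consensus[f]))
  }
})

test_that("generate_reference is byte-deterministic and errors when too small", {
  d1 <- file.path(tempdir(), "refA")
  d2 <- file.path(tempdir(), "refB")
  generate_reference(small_config(seed = 3), d1)
  generate_reference(small_config(seed = 3), d2)
  for (f in c("genome.fa", "mirna.gff3", "structural.bed", "cisnat.bed",
              "te_copies.bed", "pirna_clusters.bed", "te_consensus.fa")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_error(generate_reference(small_config(genome_length = 3000)),
               "sizing error")
})

test_that("simulate_library output matches its truth sidecar exactly", {
  sim <- small_sim()
  man <- sim$manifest
  fq <- parse_fastq_fixture(man$fastq[1])
  truth <- read_stage_tsv(man$truth[1])
  expect_equal(length(fq$seq), nrow(truth))
  expect_equal(fq$id, truth$read_id)
  # raw read = insert + adapter + filler at the configured raw length
  expect_true(all(nchar(fq$seq) == sim$config$raw_read_length))
  expect_true(all(startsWith(fq$seq, paste0(truth$insert,
                                            sim$config$adapter))))
  expect_error(simulate_library(sim$bundle, sim$config, sim$truth,
                                "nope", tempdir()),
               "unknown design point")
})

test_that("same seed gives byte-identical libraries; different replicates differ", {
  sim <- small_sim()
  again <- simulate_library(sim$bundle, sim$config, sim$truth,
                            sim$manifest$library_id[1],
                            file.path(tempdir(), "relib"))
  expect_identical(readLines(again$fastq), readLines(sim$manifest$fastq[1]))
  expect_false(identical(readLines(sim$manifest$fastq[1]),
                         readLines(sim$manifest$fastq[2])))
})

test_that("degenerate isoform mixture yields only exact mature sequences", {
  cfg <- small_config(seed = 5,
                      isoform_fractions = c(canonical = 1, noncanonical = 0,
                                            nta = 0),
                      frac_internal_mismatch = 0)
  b <- generate_reference(cfg)
  tt <- truth_table(cfg)
  sim <- simulate_library(b, cfg, tt, "wt.F2_4h.r1",
                          file.path(tempdir(), "degen"))
  mir <- sim$truth[sim$truth$source_class == "mirna", ]
  expect_gt(nrow(mir), 0)
  expect_true(all(mir$isoform == "canonical"))
  mat <- stats::setNames(b$mirna$mature_seq, b$mirna$mirna_id)
  expect_equal(mir$insert, unname(mat[mir$source_id]))
})

test_that("planted tail frequencies are recovered within 3 sigma", {
  freqs <- c(A = 0.5, AA = 0.2, U = 0.3)
  cfg <- small_config(seed = 6, library_depth_mean = 20000,
                      nta_tail_freqs = freqs,
                      isoform_fractions = c(canonical = 0.3,
                                            noncanonical = 0.1, nta = 0.6),
                      force_nontemplated = FALSE)
  b <- generate_reference(cfg)
  tt <- truth_table(cfg)
  tails <- character(0)
  for (lib in c("wt.F2_4h.r1", "wt.F2_4h.r2", "mut.UF0_2h.r1")) {
    sim <- simulate_library(b, cfg, tt, lib, file.path(tempdir(), "tails"))
    tails <- c(tails, sim$truth$tail[sim$truth$isoform %in% "nta"])
  }
  n <- length(tails)
  expect_gt(n, 1500)
  for (tl in names(freqs)) {
    phat <- mean(tails == tl)
    se <- sqrt(freqs[[tl]] * (1 - freqs[[tl]]) / n)
    expect_lt(abs(phat - freqs[[tl]]), 3 * se + 1e-12, label = tl)
  }
})

test_that("planted class profiles reproduce configured means within NB error", {
  sim <- small_sim()
  cfg <- sim$config
  prof <- sim$truth$profiles
  # pool miRNA read counts per (mirna, genotype, timepoint) over replicates
  for (lib in sim$manifest$library_id) {
    truth <- read_stage_tsv(sim$manifest$truth[sim$manifest$library_id == lib])
    dp <- sim$manifest[sim$manifest$library_id == lib, ]
    mir <- truth[truth$source_class == "mirna" &
                   truth$isoform != "decoy_internal", ]
    obs <- table(factor(mir$source_id, levels = sim$truth$mirnas$mirna_id))
    key <- prof$genotype == dp$genotype & prof$timepoint == dp$timepoint
    mu <- prof$mean_rpm[key][match(names(obs), prof$mirna_id[key])] *
      cfg$library_depth_mean / 1e6
    # 5-sigma NB band per miRNA (counts are small; skip tiny means)
    big <- mu >= 5
    sd_nb <- sqrt(mu + cfg$nb_dispersion * mu^2)
    expect_true(all(abs(as.numeric(obs)[big] - mu[big]) <
                      5 * sd_nb[big] + 5), label = lib)
  }
})
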