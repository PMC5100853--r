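# annotate module: priority order, length rules, composition, clusters.

toy_reads <- function(seqs, counts = rep(1L, length(seqs))) {
  data.frame(sequence = seqs, count = counts, stringsAsFactors = FALSE)
}

test_that("priority order: miRNA beats exon; structural beats TE", {
  b <- toy_bundle()
  g <- unname(b$genome)
  reads <- toy_reads(c(
    substr(g, 116, 137),   # inside hairpin AND the overlapping exon -> miRNA
    substr(g, 320, 341),   # tRNA locus -> structural
    substr(g, 1010, 1031), # plain exon
    substr(g, 1110, 1131), # intron
    substr(g, 10, 31)      # intergenic
  ))
  ann <- annotate_reads(reads, b)$annotation
  expect_equal(ann$class,
               c("miRNA", "structural_smallRNA", "exon", "intron",
                 "intergenic"))
  expect_equal(ann$subtype[2], "tRNA")
})

test_that("cis-NAT requires 21 nt; TE subtypes split by read length", {
  b <- toy_bundle()
  g <- unname(b$genome)
  reads <- toy_reads(c(
    substr(g, 620, 640),   # 21 nt in the cis-NAT overlap -> cisNAT
    substr(g, 620, 641),   # 22 nt, same locus -> falls through (intergenic)
    substr(g, 860, 880),   # 21 nt on TE -> TE-siRNA
    substr(g, 860, 881),   # 22 nt on TE -> TE, no subtype
    substr(g, 860, 884)    # 25 nt on TE -> TE-piRNA
  ))
  ann <- annotate_reads(reads, b)$annotation
  expect_equal(ann$class[1], "cisNAT")
  expect_equal(ann$subtype[1], "cisNAT-siRNA")
  expect_equal(ann$class[2], "intergenic")
  expect_equal(ann$class[3:5], rep("TE", 3))
  expect_equal(ann$subtype[3:5], c("TE-siRNA", NA, "TE-piRNA"))
})

test_that("minus-strand reads on a sense-required layer fall through", {
  b <- toy_bundle()
  g <- unname(b$genome)
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  ann <- annotate_reads(toy_reads(rc(substr(g, 320, 341))), b)$annotation
  expect_false(ann$class == "structural_smallRNA")
})

test_that("priority monotonicity: adding lower-priority layers never changes classes", {
  sim <- small_sim()
  proc <- process_fastq(sim$manifest$fastq[3], sim$config$adapter)
  idx <- build_index(sim$bundle$genome)
  hits <- query_index(idx, proc$reads$sequence)
  full <- annotate_reads(proc$reads, sim$bundle, hits = hits)$annotation
  stripped <- sim$bundle
  stripped$layers$exon <- stripped$layers$exon[0]
  stripped$layers$intron <- stripped$layers$intron[0]
  part <- annotate_reads(proc$reads, stripped, hits = hits)$annotation
  higher <- !full$class %in% c("exon", "intron", "intergenic")
  expect_equal(part$class[higher], full$class[higher])
})

test_that("class composition sums to 1 and recovers the planted mixture", {
  sim <- small_sim()
  idx <- build_index(sim$bundle$genome)
  proc <- process_fastq(sim$manifest$fastq[1], sim$config$adapter)
  ann <- annotate_reads(proc$reads, sim$bundle, index = idx)
  comp <- class_composition(ann$annotation)
  expect_equal(sum(comp$fraction), 1)
  truth <- read_stage_tsv(sim$manifest$truth[1])
  truth <- truth[!truth$low_quality, ]
  n <- nrow(truth)
  # planted structural share, 3-sigma binomial band (annotation may differ
  # for reads that happen to overlap a higher layer, so compare classes
  # that are unambiguous by construction)
  p_st <- mean(truth$source_class == "structural")
  got_st <- sum(comp$reads[comp$class == "structural_smallRNA"]) /
    sum(comp$reads)
  expect_lt(abs(got_st - p_st), 3 * sqrt(p_st * (1 - p_st) / n) + 0.01)
  expect_error(class_composition(ann$annotation[0, ]), "empty")
})

test_that("miRNA-only library gives miRNA fraction 1", {
  b <- toy_bundle()
  reads <- toy_reads(b$mirna$mature_seq, counts = 50L)
  comp <- class_composition(annotate_reads(reads, b)$annotation)
  expect_equal(comp$class, "miRNA")
  expect_equal(comp$fraction, 1)
  expect_equal(comp$reads, 50)
})

test_that("piRNA cluster distribution assigns weighted reads per cluster", {
  b <- toy_bundle()
  g <- unname(b$genome)
  reads <- toy_reads(c(substr(g, 860, 884),    # 25 nt piRNA inside cluster1
                       substr(g, 860, 880)),   # 21 nt siRNA inside cluster1
                     counts = c(10L, 4L))
  ann <- annotate_reads(reads, b)
  d <- pirna_cluster_distribution(ann$annotation, ann$hits, b$clusters)
  expect_equal(d$reads[d$cluster == "cluster1" & d$subtype == "TE-piRNA"], 10)
  expect_equal(d$reads[d$cluster == "cluster1" & d$subtype == "TE-siRNA"], 4)
  # empty cluster annotation: everything lands outside
  d0 <- pirna_cluster_distribution(ann$annotation, ann$hits,
                                   GenomicRanges::GRanges())
  expect_true(all(d0$cluster == "outside"))
  expect_equal(sum(d0$reads), 14)
})

test_that("planted two-cluster split is recovered within sampling error", {
  sim <- small_sim()
  idx <- build_index(sim$bundle$genome)
  proc <- process_fastq(sim$manifest$fastq[4], sim$config$adapter)
  ann <- annotate_reads(proc$reads, sim$bundle, index = idx)
  d <- pirna_cluster_distribution(ann$annotation, ann$hits,
                                  sim$bundle$clusters)
  truth <- read_stage_tsv(sim$manifest$truth[4])
  truth <- truth[!truth$low_quality &
                   truth$source_class %in% c("te_sirna", "te_pirna"), ]
  # families TE1-TE2 lie in cluster1, TE3 in cluster2, TE4 outside
  fam <- sub("_copy.*", "", truth$source_id)
  planted <- c(cluster1 = sum(fam %in% c("TE1", "TE2")),
               cluster2 = sum(fam == "TE3"),
               outside = sum(fam == "TE4"))
  got <- tapply(d$reads, d$cluster, sum)[names(planted)]
  expect_equal(as.vector(got), unname(planted), tolerance = 0.1)
})

test_that("weight conservation over a whole library", {
  sim <- small_sim()
  proc <- process_fastq(sim$manifest$fastq[5], sim$config$adapter)
  ann <- annotate_reads(proc$reads, sim$bundle)
  h <- ann$hits
  mass <- sum(h$weight * proc$reads$count[h$query])
  mapped <- sum(proc$reads$count[unique(h$query)])
  expect_equal(mass, mapped)
})
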