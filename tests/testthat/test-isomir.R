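# isomiR module: window construction, templated classification, the NTA
# algorithm, quantification, summaries and distributions.

test_that("build_mirna_refs reproduces the generator's annotation", {
  sim <- small_sim()
  p <- sim$bundle$paths
  refs <- build_mirna_refs(p$gff3, p$hairpin, p$mature)
  cols <- c("mirna_id", "chrom", "hp_start", "hp_end", "mat_start",
            "mat_end", "win_start", "win_end", "mature_seq", "hairpin_seq")
  expect_equal(refs[, cols], sim$bundle$mirna[, cols], ignore_attr = TRUE)
})

test_that("window arithmetic: 2 nt at 5', 5 nt at 3', clipped with warning", {
  dir <- tempdir()
  gff <- file.path(dir, "w.gff3")
  writeLines(c(
    "##gff-version 3",
    "c\tx\tmiRNA_primary_transcript\t100\t179\t.\t+\t.\tID=hp1;Name=hp1",
    "c\tx\tmiRNA\t110\t131\t.\t+\t.\tID=m1;Name=m1;Derives_from=hp1",
    "c\tx\tmiRNA_primary_transcript\t300\t379\t.\t+\t.\tID=hp2;Name=hp2",
    "c\tx\tmiRNA\t300\t321\t.\t+\t.\tID=m2;Name=m2;Derives_from=hp2"
  ), gff)
  hp <- stats::setNames(strrep("A", c(80, 80)), c("hp1", "hp2"))
  mat <- stats::setNames(strrep("A", c(22, 22)), c("m1", "m2"))
  fh <- file.path(dir, "h.fa"); fm <- file.path(dir, "m.fa")
  mirmzt:::.write_fasta(hp, fh)
  mirmzt:::.write_fasta(mat, fm)
  expect_warning(refs <- build_mirna_refs(gff, fh, fm), "clipped")
  expect_equal(refs$win_start, c(108L, 300L))  # m2 clipped at hairpin start
  expect_equal(refs$win_end, c(136L, 326L))
  # mature outside hairpin -> validation error
  writeLines(c(
    "##gff-version 3",
    "c\tx\tmiRNA_primary_transcript\t100\t150\t.\t+\t.\tID=hp1;Name=hp1",
    "c\tx\tmiRNA\t140\t161\t.\t+\t.\tID=m1;Name=m1;Derives_from=hp1"
  ), gff)
  expect_error(build_mirna_refs(gff, fh, fm), "not contained")
})

test_that("templated classification: canonical, window variants, out-of-window", {
  b <- toy_bundle()
  g <- unname(b$genome)
  idx <- build_index(b$genome)
  m <- b$mirna
  reads <- data.frame(sequence = c(
    m$mature_seq,                        # exact mature -> canonical
    substr(g, 116, 139),                 # +2 templated 3' nt -> noncanonical
    substr(g, 114, 137),                 # -2 templated 5' nt -> noncanonical
    substr(g, 118, 137),                 # truncation inside window -> noncan
    substr(g, 113, 137),                 # 3 nt upstream -> outside window
    substr(g, 116, 143)                  # +6 at 3' -> outside window
  ), count = 1L, stringsAsFactors = FALSE)
  calls <- classify_reads(reads, m, idx)
  got <- calls$isoform[match(reads$sequence, calls$sequence)]
  expect_equal(got[1:4], c("canonical", rep("noncanonical", 3)))
  expect_true(all(is.na(got[5:6])))  # unassigned: no call rows
  expect_true(all(calls$mirna_id == "mir-t1"))
})

test_that("NTA detection: patterns MMX/MXX/XXX accepted, others rejected", {
  b <- toy_bundle()
  g <- unname(b$genome)
  idx <- build_index(b$genome)
  m <- b$mirna
  mat <- m$mature_seq
  # template bases just 3' of the mature end (hairpin continues)
  t1 <- substr(g, 138, 138); t2 <- substr(g, 139, 139)
  x1 <- mismatch_base(g, 138)  # mismatching tail base at position +1
  x2 <- mismatch_base(g, 139)
  x3 <- mismatch_base(g, 140)
  reads <- data.frame(sequence = c(
    paste0(mat, x1),              # 1-nt non-templated tail  -> MMX
    paste0(mat, x1, x2),          # 2-nt tail                -> MXX
    paste0(mat, x1, x2, x3),      # 3-nt tail                -> XXX
    paste0(mat, t1, x2),          # first tail base templated -> M X M? no:
                                  # trimming realigns body+t1; pattern MMX
    paste0(mat, t1, t2)           # fully templated extension: perfect match
  ), count = 1L, stringsAsFactors = FALSE)
  calls <- classify_reads(reads, m, idx)
  got <- calls[match(reads$sequence, calls$sequence), ]
  expect_equal(got$isoform[1:3], rep("nta", 3))
  expect_equal(got$match_pattern[1:3], c("MMX", "MXX", "XXX"))
  expect_equal(got$tail[1:3],
               chartr("T", "U", c(x1, paste0(x1, x2),
                                  paste0(x1, x2, x3))))
  # read 4: the mismatch suffix is only the last base -> MMX with 1-nt tail
  expect_equal(got$isoform[4], "nta")
  expect_equal(got$match_pattern[4], "MMX")
  expect_equal(got$tail[4], chartr("T", "U", x2))
  # read 5 is a perfect genomic match inside the window -> noncanonical
  expect_equal(got$isoform[5], "noncanonical")
})

test_that("NTA rejects interior mismatches and honors the perfect-match rule", {
  b <- toy_bundle()
  g <- unname(b$genome)
  idx <- build_index(b$genome)
  m <- b$mirna
  mat <- m$mature_seq
  # interior mismatch at position 5: not a tail; trimmed read still
  # imperfect -> no NTA call
  q <- mat
  substr(q, 5, 5) <- mismatch_base(g, 120)
  calls <- detect_nta(data.frame(sequence = q, count = 1L), m, idx)
  expect_equal(nrow(calls), 0)
  # pattern XMX (mismatch, match, mismatch in last 3) must be rejected
  q2 <- paste0(mat, mismatch_base(g, 138), substr(g, 139, 139))
  q2 <- paste0(q2, mismatch_base(g, 140))
  # build it explicitly: last3 = (mismatch, template match, mismatch)
  calls2 <- detect_nta(data.frame(sequence = q2, count = 1L), m, idx)
  expect_equal(nrow(calls2), 0)
  # trimmed body < 15 nt cannot anchor
  short <- paste0(substr(mat, 1, 16), "A")
  expect_equal(nrow(detect_nta(data.frame(sequence = short, count = 1L),
                               m, idx)), 0)
})

test_that("trim-realign consistency: removing the tail yields a templated call", {
  sim <- small_sim()
  idx <- build_index(sim$bundle$genome)
  proc <- process_fastq(sim$manifest$fastq[8], sim$config$adapter)
  calls <- classify_reads(proc$reads, sim$bundle$mirna, idx)
  nta <- calls[calls$isoform == "nta", ]
  expect_gt(nrow(nta), 10)
  bodies <- substr(nta$sequence, 1,
                   nchar(nta$sequence) - nchar(nta$tail))
  body_calls <- classify_reads(
    data.frame(sequence = unique(bodies), count = 1L), sim$bundle$mirna,
    idx)
  expect_true(all(unique(bodies) %in% body_calls$sequence))
  expect_true(all(body_calls$isoform %in% c("canonical", "noncanonical")))
})

test_that("full truth-sidecar recovery on a simulated library", {
  sim <- small_sim()
  idx <- build_index(sim$bundle$genome)
  lib <- 7
  proc <- process_fastq(sim$manifest$fastq[lib], sim$config$adapter)
  calls <- classify_reads(proc$reads, sim$bundle$mirna, idx)
  truth <- read_stage_tsv(sim$manifest$truth[lib])
  truth <- truth[!truth$low_quality & truth$source_class == "mirna", ]
  # per-isoform totals agree exactly with the planted truth
  got <- quantify_isoforms(calls, sim$bundle$mirna$mirna_id)
  planted <- table(factor(truth$isoform,
                          c("canonical", "noncanonical", "nta")))
  expect_equal(unname(colSums(got)), as.vector(planted))
  # per-miRNA canonical counts agree
  pc <- table(factor(truth$source_id[truth$isoform == "canonical"],
                     rownames(got)))
  expect_equal(unname(got[, "canonical"]), as.vector(pc))
  # planted tails recovered read-for-read
  tt <- truth[truth$isoform == "nta", ]
  key <- paste(tt$insert, tt$tail)
  ck <- paste(calls$sequence, calls$tail)[calls$isoform == "nta"]
  expect_true(all(key %in% ck))
})

test_that("quantify_isoforms keeps absent miRNAs as zero rows", {
  m <- quantify_isoforms(
    data.frame(sequence = "A", count = 100, mirna_id = "mir-x",
               isoform = "canonical", tail = "", match_pattern = "",
               weight = 1), c("mir-x", "mir-y"))
  expect_equal(m["mir-x", ], c(canonical = 100, noncanonical = 0, nta = 0))
  expect_equal(unname(m["mir-y", ]), c(0, 0, 0))
})

test_that("isoform percentage arithmetic matches the published table shape", {
  p <- isoform_percentages(c(103105.0, 744043.2), c(13902.3, 92198.8),
                           c(32837.7, 63846.7))
  expect_equal(p$canonical_pct, c(68.8, 82.7))
  expect_equal(p$nta_pct[1], 21.9)
  # single nonzero component -> 100%
  p1 <- isoform_percentages(5, 0, 0)
  expect_equal(p1$canonical_pct, 100.0)
})

test_that("distributions return normalized tables and tolerate no NTA", {
  calls <- data.frame(
    sequence = c(strrep("T", 22), strrep("T", 22), strrep("G", 24)),
    count = c(6, 4, 10), mirna_id = "m",
    isoform = c("canonical", "canonical", "nta"),
    tail = c("", "", "AA"), match_pattern = "", weight = 1)
  d <- isoform_distributions(calls)
  expect_equal(sum(d$length), 1)
  expect_equal(unname(d$length[c("22", "24")]), c(0.5, 0.5))
  expect_equal(unname(d$first_nt["U"]), 1)
  expect_equal(unname(d$tail["AA"]), 1)
  d0 <- isoform_distributions(calls[calls$isoform == "canonical", ])
  expect_length(d0$tail, 0)
})
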