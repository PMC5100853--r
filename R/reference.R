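# Synthetic-data module: toy reference bundle (genome + annotation layers).

# Fixed 30-nt stand-in for the 2S rRNA sequence (synthetic, arbitrary); having
# one constant, highly abundant structural sequence lets depletion be tested.
SYNTHETIC_2S_SEQ <- "TGCTTGGACTACATATGGTTGAGGGTTGTA"

.preserve_rng <- function(expr, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Generate the toy reference bundle
#'
#' Builds a random genome of `config$genome_length` bases on one contig
#' (`chrT`) and places, left to right with random gaps: miRNA hairpins (80 nt,
#' one 22-nt mature arm at a fixed offset, so every mature lies strictly
#' inside its hairpin), structural-RNA loci (the first is a 2S-rRNA-like
#' constant sequence), overlapping antisense (cis-NAT) transcript pairs,
#' transposon consensus copies (two identical genomic insertions per family,
#' so TE reads multi-map), standalone exons and introns, and piRNA clusters
#' spanning a subset of TE copies.  One extra exon annotation is laid over the
#' first hairpin so that annotation layers genuinely overlap and the priority
#' rules are exercised.
#'
#' Deterministic given `config$seed`; the caller's RNG state is untouched.
#'
#' @param config a [simulation_config()].
#' @param out_dir if non-NULL, write genome FASTA, miRNA GFF3 (miRBase
#'   dialect), BED6 layers and TE consensus FASTA there.
#' @return a `ReferenceBundle` list.
#' @export
generate_reference <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .preserve_rng(.generate_reference_impl(config, out_dir), config$seed)
}

.generate_reference_impl <- function(config, out_dir) {
  chrom <- "chrT"
  L <- config$genome_length
  n_mir <- 5L * config$n_mirnas_per_class
  hp_len <- 80L
  mat_off <- 16L   # 1-based offset of the mature 5' end within the hairpin
  mat_len <- 22L

  cursor <- 1L
  gap <- function() sample(60:200, 1L)

  take <- function(len) {
    start <- cursor + gap()
    end <- start + len - 1L
    if (end > L) {
      stop("genome_length too small to place all features (sizing error)")
    }
    cursor <<- end
    c(start, end)
  }

  # --- miRNA hairpins -------------------------------------------------------
  mir_ids <- sprintf("mir-%03d", seq_len(n_mir))
  hp <- t(vapply(seq_len(n_mir), function(i) take(hp_len), integer(2)))
  mirna <- data.frame(
    mirna_id = mir_ids,
    hairpin_id = paste0("hp-", mir_ids),
    chrom = chrom, strand = "+",
    hp_start = hp[, 1], hp_end = hp[, 2],
    mat_start = hp[, 1] + mat_off - 1L,
    mat_end = hp[, 1] + mat_off + mat_len - 2L,
    stringsAsFactors = FALSE
  )

  # --- structural RNA loci --------------------------------------------------
  subtypes <- c("rRNA", rep(c("tRNA", "rRNA", "snoRNA", "snRNA", "ncRNA"),
                            length.out = max(config$n_structural_loci - 1L, 0)))
  st_len <- c(nchar(SYNTHETIC_2S_SEQ),
              sample(80:200, config$n_structural_loci - 1L, replace = TRUE))
  st <- t(vapply(st_len, function(l) take(as.integer(l)), integer(2)))
  structural <- data.frame(
    name = c("rRNA_2S",
             sprintf("%s_%02d", subtypes[-1], seq_len(nrow(st) - 1L))),
    subtype = subtypes,
    start = st[, 1], end = st[, 2], stringsAsFactors = FALSE
  )

  # --- cis-NAT pairs (two 600-nt transcripts overlapping by 200) -----------
  cis <- vector("list", config$n_cisnat_pairs)
  for (i in seq_len(config$n_cisnat_pairs)) {
    span <- take(1000L)
    cis[[i]] <- data.frame(
      name = sprintf("cisnat_%02d_%s", i, c("A", "B")),
      pair = sprintf("cisnat_%02d", i),
      start = c(span[1], span[1] + 400L),
      end = c(span[1] + 599L, span[2]),
      strand = c("+", "-"), stringsAsFactors = FALSE
    )
  }
  cisnat <- do.call(rbind, cis)

  # --- TE families: 2 identical genomic copies each ------------------------
  te_len <- 400L
  n_te <- config$n_te_families
  te_fams <- sprintf("TE%d", seq_len(n_te))
  te_copies <- vector("list", n_te * 2L)
  k <- 0L
  cluster_spans <- list()
  open_cluster <- function(fams_here) {
    starts <- ends <- integer(0)
    for (f in fams_here) {
      for (cp in 1:2) {
        k <<- k + 1L
        pos <- take(te_len)
        te_copies[[k]] <<- data.frame(
          name = sprintf("%s_copy%d", f, cp), family = f,
          start = pos[1], end = pos[2], stringsAsFactors = FALSE
        )
        starts <- c(starts, pos[1]); ends <- c(ends, pos[2])
      }
    }
    c(min(starts) - 50L, max(ends) + 50L)
  }
  in_c1 <- te_fams[seq_len(min(2L, n_te))]
  in_c2 <- if (n_te >= 3L) te_fams[3L] else character(0)
  outside <- setdiff(te_fams, c(in_c1, in_c2))
  cluster_spans$cluster1 <- open_cluster(in_c1)
  if (length(in_c2)) cluster_spans$cluster2 <- open_cluster(in_c2)
  for (f in outside) open_cluster(f)  # span unused
  te_copies <- do.call(rbind, te_copies[seq_len(k)])
  clusters <- data.frame(
    name = names(cluster_spans),
    start = vapply(cluster_spans, `[`, numeric(1), 1),
    end = vapply(cluster_spans, `[`, numeric(1), 2),
    stringsAsFactors = FALSE
  )

  # --- exons / introns ------------------------------------------------------
  ex <- t(vapply(1:6, function(i) take(300L), integer(2)))
  exon <- data.frame(name = sprintf("exon_%02d", 1:6),
                     start = ex[, 1], end = ex[, 2], stringsAsFactors = FALSE)
  # overlapping annotation: an exon over the first hairpin (priority test bed)
  exon <- rbind(exon, data.frame(name = "exon_mir_overlap",
                                 start = mirna$hp_start[1] - 20L,
                                 end = mirna$hp_end[1] + 20L))
  it <- t(vapply(1:4, function(i) take(250L), integer(2)))
  intron <- data.frame(name = sprintf("intron_%02d", 1:4),
                       start = it[, 1], end = it[, 2],
                       stringsAsFactors = FALSE)

  # --- genome sequence ------------------------------------------------------
  genome <- .rand_dna(L)
  te_seqs <- stats::setNames(
    vapply(te_fams, function(f) .rand_dna(te_len), character(1)), te_fams)
  splice_in <- function(genome, start, seq) {
    paste0(substr(genome, 1, start - 1L), seq,
           substr(genome, start + nchar(seq), L))
  }
  for (i in seq_len(nrow(te_copies))) {
    genome <- splice_in(genome, te_copies$start[i],
                        te_seqs[[te_copies$family[i]]])
  }
  genome <- splice_in(genome, structural$start[1], SYNTHETIC_2S_SEQ)
  stopifnot(nchar(genome) == L)

  mirna$hairpin_seq <- .substr_vec(genome, mirna$hp_start, mirna$hp_end)
  mirna$mature_seq <- .substr_vec(genome, mirna$mat_start, mirna$mat_end)

  gr <- function(df, strand = "+") {
    g <- GenomicRanges::GRanges(chrom,
                                IRanges::IRanges(df$start, df$end),
                                strand = if ("strand" %in% names(df)) {
                                  df$strand
                                } else strand)
    for (cc in setdiff(names(df), c("start", "end", "strand"))) {
      S4Vectors::mcols(g)[[cc]] <- df[[cc]]
    }
    g
  }

  layers <- list(
    structural = gr(structural),
    cisnat = gr(cisnat),
    te = gr(te_copies),
    exon = gr(exon),
    intron = gr(intron)
  )

  # free (intergenic) space = complement of every annotated feature
  all_feat <- c(
    GenomicRanges::reduce(GenomicRanges::GRanges(
      chrom, IRanges::IRanges(mirna$hp_start, mirna$hp_end))),
    GenomicRanges::reduce(unlist(GenomicRanges::GRangesList(
      lapply(layers, function(g) {
        GenomicRanges::GRanges(chrom, IRanges::IRanges(
          GenomicRanges::start(g), GenomicRanges::end(g)))
      }))))
  )
  red <- GenomicRanges::reduce(all_feat, ignore.strand = TRUE)
  s <- GenomicRanges::start(red)
  e <- GenomicRanges::end(red)
  fs <- c(1L, e + 1L)
  fe <- c(s - 1L, L)
  keep <- (fe - fs) >= 50L
  free <- GenomicRanges::GRanges(chrom, IRanges::IRanges(fs[keep], fe[keep]))

  bundle <- list(
    chrom = chrom,
    genome = stats::setNames(genome, chrom),
    mirna = .add_windows(mirna),
    layers = layers,
    clusters = gr(clusters, strand = "*"),
    te_consensus = te_seqs,
    free = free,
    paths = NULL
  )
  class(bundle) <- "ReferenceBundle"

  if (!is.null(out_dir)) {
    bundle <- write_reference(bundle, out_dir)
  }
  bundle
}

# noncanonical window: 2 nt upstream of the mature 5' end, 5 nt downstream of
# the 3' end, clipped to the hairpin bounds (clipping is reported).
.add_windows <- function(mirna) {
  mirna$win_start <- pmax(mirna$mat_start - 2L, mirna$hp_start)
  mirna$win_end <- pmin(mirna$mat_end + 5L, mirna$hp_end)
  clipped <- (mirna$mat_start - 2L < mirna$hp_start) |
    (mirna$mat_end + 5L > mirna$hp_end)
  if (any(clipped)) {
    warning(sprintf("noncanonical window clipped to hairpin bounds for: %s",
                    paste(mirna$mirna_id[clipped], collapse = ", ")))
  }
  mirna
}

#' Write a reference bundle to disk
#'
#' Emits `genome.fa`, `mirna.gff3` (miRBase dialect: pre-miRNA features with
#' mature `miRNA` children linked by `Derives_from`), BED6 layers
#' (`structural.bed`, `cisnat.bed`, `te_copies.bed`, `exon.bed`,
#' `intron.bed`, `pirna_clusters.bed`) and `te_consensus.fa`.
#'
#' @param bundle a `ReferenceBundle`.
#' @param out_dir output directory (created if needed).
#' @return the bundle with `$paths` filled in.
#' @export
write_reference <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- list(
    genome = file.path(out_dir, "genome.fa"),
    gff3 = file.path(out_dir, "mirna.gff3"),
    structural = file.path(out_dir, "structural.bed"),
    cisnat = file.path(out_dir, "cisnat.bed"),
    te_copies = file.path(out_dir, "te_copies.bed"),
    exon = file.path(out_dir, "exon.bed"),
    intron = file.path(out_dir, "intron.bed"),
    clusters = file.path(out_dir, "pirna_clusters.bed"),
    te_consensus = file.path(out_dir, "te_consensus.fa"),
    hairpin = file.path(out_dir, "hairpin.fa"),
    mature = file.path(out_dir, "mature.fa")
  )
  .write_fasta(bundle$genome, p$genome)
  .write_mirbase_gff3(bundle$mirna, p$gff3)
  .write_bed(bundle$layers$structural, p$structural)
  .write_bed(bundle$layers$cisnat, p$cisnat)
  .write_bed(bundle$layers$te, p$te_copies)
  .write_bed(bundle$layers$exon, p$exon)
  .write_bed(bundle$layers$intron, p$intron)
  .write_bed(bundle$clusters, p$clusters)
  .write_fasta(bundle$te_consensus, p$te_consensus)
  .write_fasta(stats::setNames(bundle$mirna$hairpin_seq,
                               bundle$mirna$hairpin_id), p$hairpin)
  .write_fasta(stats::setNames(bundle$mirna$mature_seq,
                               bundle$mirna$mirna_id), p$mature)
  bundle$paths <- p
  bundle
}

.write_mirbase_gff3 <- function(mirna, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(mirna))) {
    lines <- c(
      lines,
      sprintf("%s\tmirmzt\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
              mirna$chrom[i], mirna$hp_start[i], mirna$hp_end[i],
              mirna$strand[i], mirna$hairpin_id[i], mirna$hairpin_id[i]),
      sprintf("%s\tmirmzt\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
              mirna$chrom[i], mirna$mat_start[i], mirna$mat_end[i],
              mirna$strand[i], mirna$mirna_id[i], mirna$mirna_id[i],
              mirna$hairpin_id[i])
    )
  }
  writeLines(lines, path)
  invisible(path)
}
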