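# isomiR module: canonical / noncanonical / 3' non-templated addition (NTA)
# classification of miRNA-locus reads, quantification and summaries.

.NTA_PATTERNS <- c("MMX", "MXX", "XXX")

#' Build miRNA annotations from miRBase-dialect files
#'
#' Reads a GFF3 with `miRNA_primary_transcript` features and nested `miRNA`
#' children (linked by `Derives_from`), plus hairpin and mature FASTA files,
#' and returns one record per mature miRNA with its noncanonical window:
#' 2 nt upstream of the mature 5' end and 5 nt downstream of the 3' end,
#' clipped to the hairpin bounds (clipping raises a warning).
#'
#' @param gff3 path to the miRNA GFF3.
#' @param hairpin_fa,mature_fa FASTA paths (hairpin and mature sequences).
#' @return data.frame with hairpin/mature/window coordinates and sequences
#'   (same shape as `ReferenceBundle$mirna`).
#' @export
build_mirna_refs <- function(gff3, hairpin_fa, mature_fa) {
  lines <- readLines(gff3)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  f <- strsplit(lines, "\t")
  stopifnot(all(lengths(f) == 9))
  df <- data.frame(
    chrom = vapply(f, `[`, character(1), 1),
    type = vapply(f, `[`, character(1), 3),
    start = as.integer(vapply(f, `[`, character(1), 4)),
    end = as.integer(vapply(f, `[`, character(1), 5)),
    strand = vapply(f, `[`, character(1), 7),
    attrs = vapply(f, `[`, character(1), 9),
    stringsAsFactors = FALSE)
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
    vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
           character(1))
  }
  df$id <- attr_val(df$attrs, "ID")
  df$derives_from <- attr_val(df$attrs, "Derives_from")
  hp <- df[df$type == "miRNA_primary_transcript", ]
  mat <- df[df$type == "miRNA", ]
  hi <- match(mat$derives_from, hp$id)
  if (anyNA(hi)) stop("mature miRNA without a parent hairpin in GFF3")
  hairpins <- .read_fasta(hairpin_fa)
  matures <- .read_fasta(mature_fa)
  out <- data.frame(
    mirna_id = mat$id, hairpin_id = mat$derives_from,
    chrom = mat$chrom, strand = mat$strand,
    hp_start = hp$start[hi], hp_end = hp$end[hi],
    mat_start = mat$start, mat_end = mat$end,
    stringsAsFactors = FALSE)
  if (any(out$mat_start < out$hp_start | out$mat_end > out$hp_end)) {
    stop("mature miRNA interval not contained in its hairpin")
  }
  out$hairpin_seq <- unname(hairpins[out$hairpin_id])
  out$mature_seq <- unname(matures[out$mirna_id])
  if (anyNA(out$hairpin_seq) || anyNA(out$mature_seq)) {
    stop("hairpin or mature sequence missing from FASTA")
  }
  .add_windows(out)
}

# per-hit templated classification against one set of mature windows;
# hits and mirna are both plus-strand genomic intervals
.templated_type <- function(hit_start, hit_end, mir) {
  same <- hit_start == mir$mat_start & hit_end == mir$mat_end
  within <- hit_start >= mir$win_start & hit_end <= mir$win_end
  ifelse(same, "canonical", ifelse(within, "noncanonical", NA_character_))
}

#' Classify collapsed reads into miRNA isoform types
#'
#' For reads with a perfect genome match: a read whose interval equals an
#' annotated mature interval is `canonical`; a read contained in the
#' noncanonical window (mature -2 nt at 5', +5 nt at 3') but not equal to the
#' mature is `noncanonical` (this includes templated truncations inside the
#' window); other mapped reads are unassigned.  A read that maps perfectly
#' anywhere in the genome is never an NTA candidate.
#'
#' Reads with no perfect genome match enter the NTA algorithm
#' ([detect_nta()]).  Assignment ties across overlapping matures are broken
#' by smallest 5'-offset to the mature start, then lexicographic miRNA id;
#' reads matching several mature loci equally are weight-split uniformly.
#'
#' @param reads data.frame with `sequence`, `count`.
#' @param mirna miRNA annotation table (`ReferenceBundle$mirna` or
#'   [build_mirna_refs()]).
#' @param index genome [build_index()].
#' @param hits optional precomputed [query_index()] hits for `reads`.
#' @return data.frame of calls: `sequence`, `count`, `mirna_id`, `isoform`
#'   (canonical/noncanonical/nta), `tail`, `match_pattern`, `weight` (one row
#'   per read x attributed miRNA; unassigned reads absent).
#' @export
classify_reads <- function(reads, mirna, index, hits = NULL) {
  if (is.null(hits)) hits <- query_index(index, reads$sequence)
  n <- nrow(reads)
  empty <- data.frame(sequence = character(0), count = numeric(0),
                      mirna_id = character(0), isoform = character(0),
                      tail = character(0), match_pattern = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)

  calls <- list()

  # ---- templated isoforms (perfect genome matches) ------------------------
  if (nrow(hits)) {
    h <- hits[hits$strand == "+", , drop = FALSE]
    if (nrow(h)) {
      win_gr <- GenomicRanges::GRanges(
        mirna$chrom, IRanges::IRanges(mirna$win_start, mirna$win_end))
      hg <- GenomicRanges::GRanges(
        h$seqname, IRanges::IRanges(h$start, h$end))
      ov <- GenomicRanges::findOverlaps(hg, win_gr, type = "within",
                                        ignore.strand = TRUE)
      if (length(ov)) {
        cand <- data.frame(
          read = h$query[S4Vectors::queryHits(ov)],
          mi = S4Vectors::subjectHits(ov),
          start = h$start[S4Vectors::queryHits(ov)],
          end = h$end[S4Vectors::queryHits(ov)])
        cand$type <- .templated_type(cand$start, cand$end,
                                     mirna[cand$mi, ])
        cand <- cand[!is.na(cand$type), , drop = FALSE]
        if (nrow(cand)) {
          # canonical beats noncanonical per read
          has_canon <- tapply(cand$type == "canonical", cand$read, any)
          keep_type <- ifelse(has_canon[as.character(cand$read)],
                              "canonical", "noncanonical")
          cand <- cand[cand$type == keep_type, , drop = FALSE]
          cand$offset <- abs(cand$start - mirna$mat_start[cand$mi])
          cand$id <- mirna$mirna_id[cand$mi]
          cand <- cand[order(cand$read, cand$offset, cand$id), ]
          # same miRNA via multiple hits: count once
          cand <- cand[!duplicated(cand[, c("read", "mi")]), , drop = FALSE]
          k <- table(cand$read)
          calls$templated <- data.frame(
            sequence = reads$sequence[cand$read],
            count = reads$count[cand$read],
            mirna_id = cand$id, isoform = cand$type,
            tail = "", match_pattern = "",
            weight = 1 / as.numeric(k[as.character(cand$read)]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }

  # ---- NTA (imperfect genome matches only) --------------------------------
  mapped <- logical(n)
  if (nrow(hits)) mapped[unique(hits$query)] <- TRUE
  unmapped <- which(!mapped)
  if (length(unmapped)) {
    nta <- detect_nta(reads[unmapped, , drop = FALSE], mirna, index)
    if (nrow(nta)) calls$nta <- nta
  }

  out <- do.call(rbind, calls)
  if (is.null(out)) empty else {
    rownames(out) <- NULL
    out
  }
}

#' Detect 3' non-templated addition (NTA) isoforms
#'
#' The tailing algorithm, applied only to reads with NO perfect genome match:
#' (1) trim the last 3 nt; (2) realign the trimmed read perfectly to the
#' genome; (3) keep hits falling within the noncanonical window of a mature
#' miRNA (mature strand); (4) realign the FULL untrimmed read, ungapped and
#' anchored at that position, against the hairpin sequence, allowing at most
#' 3 mismatches, with positions running past the hairpin 3' end counted as
#' mismatches; (5) require every mismatch to lie in the 3'-most three
#' positions and the last-three match flags to form one of the patterns
#' MMX, MXX, XXX.  The tail is the contiguous mismatching suffix (length 1,
#' 2 or 3).  Trimmed reads shorter than 15 nt cannot be anchored and are
#' skipped.
#'
#' @param reads data.frame with `sequence`, `count` (imperfectly matching
#'   reads).
#' @param mirna miRNA annotation table.
#' @param index genome [build_index()].
#' @return data.frame of NTA calls (same shape as [classify_reads()] output).
#' @export
detect_nta <- function(reads, mirna, index) {
  empty <- data.frame(sequence = character(0), count = numeric(0),
                      mirna_id = character(0), isoform = character(0),
                      tail = character(0), match_pattern = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  len <- nchar(reads$sequence)
  ok <- which(len - 3L >= 15L)
  if (!length(ok)) return(empty)
  trimmed <- substr(reads$sequence[ok], 1L, len[ok] - 3L)
  th <- query_index(index, trimmed)
  th <- th[th$strand == "+", , drop = FALSE]
  if (!nrow(th)) return(empty)
  win_gr <- GenomicRanges::GRanges(
    mirna$chrom, IRanges::IRanges(mirna$win_start, mirna$win_end))
  tg <- GenomicRanges::GRanges(th$seqname, IRanges::IRanges(th$start, th$end))
  ov <- GenomicRanges::findOverlaps(tg, win_gr, type = "within",
                                    ignore.strand = TRUE)
  if (!length(ov)) return(empty)

  cand <- data.frame(
    ridx = ok[th$query[S4Vectors::queryHits(ov)]],
    mi = S4Vectors::subjectHits(ov),
    start = th$start[S4Vectors::queryHits(ov)])
  cand <- cand[!duplicated(cand[, c("ridx", "mi", "start")]), , drop = FALSE]

  res <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    mi <- cand$mi[i]
    read <- reads$sequence[cand$ridx[i]]
    start_in_hp <- cand$start[i] - mirna$hp_start[mi] + 1L
    al <- .hamming_at(read, mirna$hairpin_seq[mi], start_in_hp)
    if (al$n_mismatches > 3L) next
    L <- nchar(read)
    if (L < 4L || !all(al$match_flags[seq_len(L - 3L)])) next
    last3 <- al$match_flags[(L - 2L):L]
    pattern <- paste(ifelse(last3, "M", "X"), collapse = "")
    if (!pattern %in% .NTA_PATTERNS) next
    tail_len <- c(MMX = 1L, MXX = 2L, XXX = 3L)[[pattern]]
    res[[i]] <- data.frame(
      ridx = cand$ridx[i], mi = mi,
      offset = abs(cand$start[i] - mirna$mat_start[mi]),
      id = mirna$mirna_id[mi],
      tail = substr(read, L - tail_len + 1L, L),
      match_pattern = pattern, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  # attribute each read to the mature with the smallest 5'-offset, then id
  res <- res[order(res$ridx, res$offset, res$id), , drop = FALSE]
  res <- res[!duplicated(res$ridx), , drop = FALSE]
  data.frame(
    sequence = reads$sequence[res$ridx],
    count = reads$count[res$ridx],
    mirna_id = res$id, isoform = "nta",
    tail = .dna2rna(res$tail), match_pattern = res$match_pattern,
    weight = 1, stringsAsFactors = FALSE)
}

#' Quantify isoform types per miRNA
#'
#' Sums weighted collapsed counts into a (miRNA x isoform) matrix; every
#' annotated miRNA keeps a row even when absent from the library.
#'
#' @param calls [classify_reads()] output for one library.
#' @param mirna_ids character vector of all annotated mature miRNA ids.
#' @return numeric matrix with rows `mirna_ids`, columns
#'   `canonical`, `noncanonical`, `nta`.
#' @export
quantify_isoforms <- function(calls, mirna_ids) {
  iso <- c("canonical", "noncanonical", "nta")
  m <- matrix(0, length(mirna_ids), 3,
              dimnames = list(mirna_ids, iso))
  if (nrow(calls)) {
    w <- calls$count * calls$weight
    for (ii in iso) {
      sel <- calls$isoform == ii
      if (!any(sel)) next
      agg <- tapply(w[sel], calls$mirna_id[sel], sum)
      m[names(agg), ii] <- as.numeric(agg)
    }
  }
  m
}

#' Percentage breakdown of isoform components
#'
#' @param canonical,noncanonical,nta per-sample-set summed RPM components.
#' @return data.frame with the three components, `total`, and percentages
#'   rounded to 1 decimal place.
#' @export
isoform_percentages <- function(canonical, noncanonical, nta) {
  total <- canonical + noncanonical + nta
  data.frame(
    canonical_rpm = canonical, noncanonical_rpm = noncanonical,
    nta_rpm = nta, total_rpm = total,
    canonical_pct = round(100 * canonical / total, 1),
    noncanonical_pct = round(100 * noncanonical / total, 1),
    nta_pct = round(100 * nta / total, 1))
}

#' Isoform summary table per sample set
#'
#' For each (genotype, timepoint) sample set: the mean over its replicate
#' libraries of the per-library total RPM of each isoform type, plus the
#' percentage each contributes to the set's total.
#'
#' @param iso_rpm list of three features x libraries RPM matrices named
#'   `canonical`, `noncanonical`, `nta` (identical column order).
#' @param design design data.frame with `library_id`, `genotype`,
#'   `timepoint` matching the matrix columns.
#' @return data.frame, one row per sample set.
#' @export
isoform_summary <- function(iso_rpm, design) {
  stopifnot(all(c("canonical", "noncanonical", "nta") %in% names(iso_rpm)))
  sets <- unique(design[, c("genotype", "timepoint")])
  comp <- vapply(seq_len(nrow(sets)), function(i) {
    libs <- design$library_id[design$genotype == sets$genotype[i] &
                                design$timepoint == sets$timepoint[i]]
    vapply(c("canonical", "noncanonical", "nta"), function(ii) {
      mean(colSums(iso_rpm[[ii]][, libs, drop = FALSE]))
    }, numeric(1))
  }, numeric(3))
  out <- isoform_percentages(comp[1, ], comp[2, ], comp[3, ])
  cbind(data.frame(dataset = sprintf("%s.%s", sets$genotype,
                                     sets$timepoint),
                   stringsAsFactors = FALSE), out)
}

#' Length, first-nucleotide and tail distributions of isoform calls
#'
#' @param calls [classify_reads()] output.
#' @return list of frequency tables (each summing to 1 when nonempty):
#'   `length` (all calls, weighted), `first_nt` (canonical calls, RNA
#'   alphabet), `tail` (NTA calls, RNA alphabet).
#' @export
isoform_distributions <- function(calls) {
  w <- calls$count * calls$weight
  freq <- function(x, wt) {
    if (!length(x)) return(numeric(0))
    agg <- tapply(wt, x, sum)
    stats::setNames(as.numeric(agg) / sum(agg), names(agg))
  }
  canon <- calls$isoform == "canonical"
  nta <- calls$isoform == "nta"
  list(
    length = freq(nchar(calls$sequence), w),
    first_nt = freq(.dna2rna(substr(calls$sequence[canon], 1, 1)), w[canon]),
    tail = freq(calls$tail[nta], w[nta])
  )
}
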