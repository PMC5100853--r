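# Annotation module: priority-ordered representative small-RNA classes,
# library composition, and piRNA-cluster distribution.

# priority order of representative classes
.CLASS_PRIORITY <- c("miRNA", "structural_smallRNA", "cisNAT", "TE",
                     "exon", "intron", "intergenic")

.hits_granges <- function(hits) {
  GenomicRanges::GRanges(hits$seqname,
                         IRanges::IRanges(hits$start, hits$end),
                         strand = hits$strand)
}

#' Annotate collapsed reads with their representative small-RNA class
#'
#' Every perfectly genome-mapped read receives exactly one representative
#' class: the highest-priority annotation layer intersected (>= 1 bp) by ANY
#' of its hits, in the order miRNA > structural small RNA (tRNA/rRNA/snoRNA/
#' snRNA/ncRNA) > cis-NAT > transposon > exon > intron > intergenic.
#' miRNA, structural, exon and intron intersection requires sense-strand
#' overlap; cis-NAT and TE layers accept either strand.  Length rules:
#' cis-NAT class requires a 21-nt read; TE reads are subtyped TE-siRNA at
#' 21 nt and TE-piRNA at >= 23 nt (22-nt TE reads carry no subtype).
#' Reads with no perfect genome hit are classed `unmapped` and excluded from
#' composition downstream.
#'
#' @param reads data.frame with `sequence` and `count` (collapsed reads).
#' @param bundle a `ReferenceBundle`.
#' @param index optional prebuilt [build_index()] of the genome.
#' @param hits optional precomputed [query_index()] result for `reads`.
#' @return list with `annotation` (per-read data.frame: sequence, count,
#'   n_hits, class, subtype) and `hits` (the hit table with weights).
#' @export
annotate_reads <- function(reads, bundle, index = NULL, hits = NULL) {
  if (is.null(hits)) {
    if (is.null(index)) index <- build_index(bundle$genome)
    hits <- query_index(index, reads$sequence)
  }
  hits <- distribute_multimappers(hits)
  n <- nrow(reads)
  read_len <- nchar(reads$sequence)

  hg <- .hits_granges(hits)
  mir_gr <- GenomicRanges::GRanges(
    bundle$mirna$chrom,
    IRanges::IRanges(bundle$mirna$hp_start, bundle$mirna$hp_end),
    strand = bundle$mirna$strand)

  overlaps_any <- function(layer, ignore_strand) {
    if (length(layer) == 0 || nrow(hits) == 0) return(logical(n))
    ov <- GenomicRanges::findOverlaps(hg, layer,
                                      ignore.strand = ignore_strand)
    res <- logical(n)
    res[unique(hits$query[S4Vectors::queryHits(ov)])] <- TRUE
    res
  }
  first_layer_hit <- function(layer, ignore_strand) {
    # index of the first overlapped layer feature per read (for subtypes)
    out <- rep(NA_integer_, n)
    if (length(layer) == 0 || nrow(hits) == 0) return(out)
    ov <- GenomicRanges::findOverlaps(hg, layer,
                                      ignore.strand = ignore_strand)
    if (!length(ov)) return(out)
    q <- hits$query[S4Vectors::queryHits(ov)]
    s <- S4Vectors::subjectHits(ov)
    keep <- !duplicated(q)
    out[q[keep]] <- s[keep]
    out
  }

  has <- list(
    miRNA = overlaps_any(mir_gr, ignore_strand = FALSE),
    structural_smallRNA = overlaps_any(bundle$layers$structural,
                                       ignore_strand = FALSE),
    cisNAT = overlaps_any(bundle$layers$cisnat, ignore_strand = TRUE) &
      read_len == 21L,
    TE = overlaps_any(bundle$layers$te, ignore_strand = TRUE),
    exon = overlaps_any(bundle$layers$exon, ignore_strand = FALSE),
    intron = overlaps_any(bundle$layers$intron, ignore_strand = FALSE)
  )
  mapped <- logical(n)
  if (nrow(hits)) mapped[unique(hits$query)] <- TRUE

  cls <- rep("unmapped", n)
  cls[mapped] <- "intergenic"
  for (layer in rev(setdiff(.CLASS_PRIORITY, "intergenic"))) {
    cls[has[[layer]]] <- layer
  }

  subtype <- rep(NA_character_, n)
  st_idx <- first_layer_hit(bundle$layers$structural, FALSE)
  sel <- cls == "structural_smallRNA"
  subtype[sel] <-
    S4Vectors::mcols(bundle$layers$structural)$subtype[st_idx[sel]]
  subtype[cls == "cisNAT"] <- "cisNAT-siRNA"
  sel <- cls == "TE"
  subtype[sel & read_len == 21L] <- "TE-siRNA"
  subtype[sel & read_len >= 23L] <- "TE-piRNA"

  annotation <- data.frame(
    sequence = reads$sequence, count = reads$count,
    n_hits = as.integer(tabulate(hits$query, nbins = n)),
    class = cls, subtype = subtype, stringsAsFactors = FALSE)
  list(annotation = annotation, hits = hits)
}

#' Small-RNA class composition of a library
#'
#' Weighted read counts and fractions per representative class over mapped
#' reads (each read contributes its full collapsed count to its single
#' representative class; fractions sum to 1).
#'
#' @param annotation the `annotation` data.frame from [annotate_reads()].
#' @return data.frame with `class`, `subtype`, `reads`, `fraction`.
#' @export
class_composition <- function(annotation) {
  ann <- annotation[annotation$class != "unmapped", , drop = FALSE]
  if (nrow(ann) == 0 || sum(ann$count) == 0) {
    stop("no mapped reads: empty library")
  }
  key <- paste(ann$class, ifelse(is.na(ann$subtype), "", ann$subtype),
               sep = "\r")
  agg <- tapply(ann$count, key, sum)
  parts <- strsplit(names(agg), "\r")
  out <- data.frame(
    class = vapply(parts, `[`, character(1), 1),
    subtype = vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                     character(1)),
    reads = as.numeric(agg),
    stringsAsFactors = FALSE)
  out$fraction <- out$reads / sum(out$reads)
  out <- out[order(match(out$class, .CLASS_PRIORITY), out$subtype), ]
  rownames(out) <- NULL
  out
}

#' Distribution of TE-derived siRNA/piRNA reads over piRNA clusters
#'
#' For TE-class reads of the siRNA (21 nt) and piRNA (>= 23 nt) subtypes,
#' sums multi-mapper-weighted collapsed counts falling inside each annotated
#' piRNA cluster; hits outside every cluster are tallied as `outside`.
#'
#' @param annotation,hits output components of [annotate_reads()].
#' @param clusters `GRanges` of piRNA cluster intervals (strand-agnostic).
#' @return data.frame with `cluster`, `subtype`, `reads`.
#' @export
pirna_cluster_distribution <- function(annotation, hits, clusters) {
  sel <- which(annotation$class == "TE" &
                 annotation$subtype %in% c("TE-siRNA", "TE-piRNA"))
  h <- hits[hits$query %in% sel, , drop = FALSE]
  cl_names <- if (length(clusters)) {
    S4Vectors::mcols(clusters)$name %||% paste0("cluster", seq_along(clusters))
  } else character(0)
  if (nrow(h) == 0) {
    return(data.frame(cluster = character(0), subtype = character(0),
                      reads = numeric(0)))
  }
  w <- h$weight * annotation$count[h$query]
  subtype <- annotation$subtype[h$query]
  assign_cl <- rep("outside", nrow(h))
  if (length(clusters)) {
    ov <- GenomicRanges::findOverlaps(.hits_granges(h), clusters,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      first <- !duplicated(S4Vectors::queryHits(ov))
      assign_cl[S4Vectors::queryHits(ov)[first]] <-
        cl_names[S4Vectors::subjectHits(ov)[first]]
    }
  }
  key <- paste(assign_cl, subtype, sep = "\r")
  agg <- tapply(w, key, sum)
  parts <- strsplit(names(agg), "\r")
  out <- data.frame(
    cluster = vapply(parts, `[`, character(1), 1),
    subtype = vapply(parts, `[`, character(1), 2),
    reads = as.numeric(agg), stringsAsFactors = FALSE)
  out[order(out$cluster, out$subtype), ]
}
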