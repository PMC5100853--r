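# Alignment module: exact-match index (bowtie -v 0 contract), bounded
# ungapped mismatch alignment, and uniform multi-mapper weight distribution.

#' Build an exact-match index over reference sequences
#'
#' The index supports lookup of all exact occurrences of a query on both
#' strands of every reference sequence (the same contract as perfect-match
#' short-read alignment).  Internally queries are grouped by width and matched
#' with Aho-Corasick preprocessed dictionaries, so lookup is linear in the
#' reference.
#'
#' @param reference named character vector, `DNAStringSet`, or FASTA path.
#' @param k seed length of the prefix hash; queries shorter than `k` fall
#'   back to a direct scan.
#' @return an `exact_index` object.
#' @export
build_index <- function(reference, k = 15L) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- .read_fasta(reference)
  }
  if (!is.character(reference)) {
    reference <- stats::setNames(as.character(reference), names(reference))
  }
  if (length(reference) == 0 || any(nchar(reference) == 0)) {
    stop("reference must be non-empty")
  }
  if (any(grepl("[^ACGTN]", reference))) {
    stop("reference contains non-ACGTN characters")
  }
  if (is.null(names(reference))) {
    names(reference) <- paste0("seq", seq_along(reference))
  }
  kmers <- lapply(reference, function(s) {
    L <- nchar(s)
    if (L < k) character(0) else substring(s, 1:(L - k + 1L), k:L)
  })
  obj <- list(seqs = reference, kmers = kmers, k = as.integer(k))
  class(obj) <- "exact_index"
  obj
}

#' Find all perfect hits of queries in an exact-match index
#'
#' @param index an [build_index()] object.
#' @param queries character vector of read sequences.
#' @return data.frame with `query` (integer index into `queries`), `seqname`,
#'   `start`, `end` (1-based closed), `strand`.  Queries containing
#'   characters outside ACGT get no hits.  A palindromic occurrence is
#'   reported on both strands.
#' @export
query_index <- function(index, queries) {
  stopifnot(inherits(index, "exact_index"))
  empty <- data.frame(query = integer(0), seqname = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  ok <- !grepl("[^ACGT]", queries) & nchar(queries) > 0
  valid <- which(ok & nchar(queries) >= index$k)
  short <- which(ok & nchar(queries) < index$k)
  out <- list()

  for (str in c("+", "-")) {
    if (!length(valid)) break
    qs <- if (str == "+") queries[valid] else .revcomp(queries[valid])
    lens <- nchar(qs)
    pref <- substr(qs, 1L, index$k)
    upref <- unique(pref)
    grp <- match(pref, upref)
    for (ci in seq_along(index$seqs)) {
      mm <- match(index$kmers[[ci]], upref)
      cand_pos <- which(!is.na(mm))
      if (!length(cand_pos)) next
      cand_id <- mm[cand_pos]
      ord <- order(cand_id)
      pos_sorted <- cand_pos[ord]
      cnt <- tabulate(cand_id, nbins = length(upref))
      offs <- cumsum(c(0L, cnt))
      npos <- cnt[grp]
      if (!sum(npos)) next
      reads_exp <- rep(seq_along(qs), npos)
      pos_exp <- pos_sorted[sequence(npos, from = offs[grp] + 1L)]
      hit <- substring(index$seqs[[ci]], pos_exp,
                       pos_exp + lens[reads_exp] - 1L) == qs[reads_exp]
      if (!any(hit)) next
      out[[length(out) + 1L]] <- data.frame(
        query = valid[reads_exp[hit]], seqname = names(index$seqs)[ci],
        start = pos_exp[hit], end = pos_exp[hit] + lens[reads_exp[hit]] - 1L,
        strand = str, stringsAsFactors = FALSE)
    }
  }

  # direct-scan fallback for queries shorter than the seed
  for (qi in short) {
    for (str in c("+", "-")) {
      q <- if (str == "+") queries[qi] else .revcomp(queries[qi])
      for (ci in seq_along(index$seqs)) {
        L <- nchar(index$seqs[[ci]])
        w <- nchar(q)
        if (w > L) next
        starts <- 1:(L - w + 1L)  # includes overlapping occurrences
        pos <- starts[substring(index$seqs[[ci]], starts,
                                starts + w - 1L) == q]
        if (!length(pos)) next
        out[[length(out) + 1L]] <- data.frame(
          query = qi, seqname = names(index$seqs)[ci],
          start = pos, end = pos + w - 1L,
          strand = str, stringsAsFactors = FALSE)
      }
    }
  }

  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$query, res$seqname, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Ungapped alignment with a bounded number of mismatches
#'
#' Scans every offset of `query` against `reference` and returns the best hit
#' (fewest mismatches, ties broken leftmost) with per-position match flags,
#' or NULL when the minimum mismatch count exceeds `max_mm` or the query is
#' longer than the reference.
#'
#' @param query,reference sequences (plus strand).
#' @param max_mm maximum allowed mismatches.
#' @return NULL, or a list with `start` (1-based offset in `reference`),
#'   `n_mismatches`, and logical `match_flags` of length `nchar(query)`.
#' @export
align_mismatch <- function(query, reference, max_mm = 3) {
  qlen <- nchar(query)
  rlen <- nchar(reference)
  if (qlen > rlen) return(NULL)
  q <- charToRaw(query)
  r <- charToRaw(reference)
  best <- NULL
  for (s in seq_len(rlen - qlen + 1L)) {
    flags <- q == r[s:(s + qlen - 1L)]
    mm <- sum(!flags)
    if (is.null(best) || mm < best$n_mismatches) {
      best <- list(start = s, n_mismatches = mm, match_flags = flags)
      if (mm == 0L) break
    }
  }
  if (best$n_mismatches > max_mm) NULL else best
}

# Ungapped comparison of `query` against `reference` anchored at `start`;
# positions running past the reference 3' end count as mismatches (they are,
# by definition, non-templated relative to the reference).
.hamming_at <- function(query, reference, start) {
  qlen <- nchar(query)
  rlen <- nchar(reference)
  q <- charToRaw(query)
  flags <- rep(FALSE, qlen)
  if (start < 1) return(list(match_flags = flags, n_mismatches = qlen))
  upto <- min(qlen, rlen - start + 1L)
  if (upto > 0) {
    r <- charToRaw(reference)
    flags[seq_len(upto)] <- q[seq_len(upto)] ==
      r[start:(start + upto - 1L)]
  }
  list(match_flags = flags, n_mismatches = sum(!flags))
}

#' Distribute multi-mapping reads uniformly across their loci
#'
#' Each of a read's k hits receives weight 1/k, so per-read weights always
#' sum to exactly 1.
#'
#' @param hits data.frame of hits with a `query` column ([query_index()]
#'   output shape).
#' @return `hits` with a `weight` column added.
#' @export
distribute_multimappers <- function(hits) {
  if (nrow(hits) == 0) {
    hits$weight <- numeric(0)
    return(hits)
  }
  k <- table(hits$query)
  hits$weight <- 1 / as.numeric(k[as.character(hits$query)])
  hits
}
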