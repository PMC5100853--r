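# Preprocess module: adapter removal, quality/length filtering, collapsing,
# and targeted sequence depletion.

# regex character class matching any phred+33 character below q_min
.low_qual_regex <- function(q_min) {
  stopifnot(q_min >= 1, q_min <= 41)
  chars <- intToUtf8(33:(32 + q_min), multiple = TRUE)
  has_dash <- "-" %in% chars
  chars <- setdiff(chars, "-")
  paste0("[", if (has_dash) "-", paste(chars, collapse = ""), "]")
}

.parse_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) {
    stop(sprintf("malformed FASTQ '%s': %d lines is not a multiple of 4",
                 path, length(lines)))
  }
  ids <- lines[c(TRUE, FALSE, FALSE, FALSE)]
  seqs <- lines[c(FALSE, TRUE, FALSE, FALSE)]
  plus <- lines[c(FALSE, FALSE, TRUE, FALSE)]
  quals <- lines[c(FALSE, FALSE, FALSE, TRUE)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+") |
                 nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop(sprintf("malformed FASTQ record %d in '%s'", bad[1], path))
  }
  list(id = sub("^@", "", ids), seq = seqs, qual = quals)
}

#' Preprocess a FASTQ library into collapsed reads
#'
#' Pipeline per read: (1) locate the first exact occurrence of the adapter
#' and remove it and everything 3' of it (no-mismatch matching; reads without
#' an adapter hit are kept whole); (2) discard reads with any remaining base
#' below `q_min` (the quality filter applies to 100% of insert nucleotides);
#' (3) discard inserts outside `[len_min, len_max]`; (4) collapse survivors
#' to unique sequences with summed counts.
#'
#' @param fastq path to a phred+33 FASTQ file.
#' @param adapter 3' adapter sequence (exact match).
#' @param q_min minimum phred quality required at every kept base.
#' @param len_min,len_max inclusive insert length bounds.
#' @return list with `reads` (data.frame `sequence`, `count`) and `stats`
#'   (single-row data.frame of raw/kept/discard tallies).
#' @export
process_fastq <- function(fastq, adapter, q_min = 20, len_min = 18,
                          len_max = 30) {
  stopifnot(nchar(adapter) > 0)
  fq <- .parse_fastq(fastq)
  n_raw <- length(fq$seq)

  hit <- Biostrings::vmatchPattern(adapter, Biostrings::DNAStringSet(fq$seq))
  first <- vapply(Biostrings::startIndex(hit),
                  function(s) if (is.null(s) || !length(s)) NA_integer_
                  else s[[1]], integer(1))
  ins_len <- ifelse(is.na(first), nchar(fq$seq), first - 1L)
  seqs <- substr(fq$seq, 1L, ins_len)
  quals <- substr(fq$qual, 1L, ins_len)

  ok_len <- ins_len >= len_min & ins_len <= len_max
  ok_qual <- !grepl(.low_qual_regex(q_min), quals, useBytes = TRUE)
  keep <- ok_len & ok_qual

  kept <- seqs[keep]
  tab <- if (length(kept)) {
    agg <- sort(table(kept), decreasing = TRUE)
    data.frame(sequence = names(agg), count = as.integer(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(sequence = character(0), count = integer(0))
  }
  stats <- data.frame(
    raw = n_raw,
    adapter_found = sum(!is.na(first)),
    fail_quality = sum(ok_len & !ok_qual),
    fail_length = sum(!ok_len),
    kept = sum(keep),
    unique_sequences = nrow(tab),
    depleted = 0L
  )
  list(reads = tab, stats = stats)
}

#' Remove reads matching a blocklist of sequences
#'
#' Drops every collapsed read whose sequence equals, or is a substring of,
#' any blocklist sequence (in-silico stand-in for experimental 2S rRNA
#' depletion).  An empty blocklist is the identity.
#'
#' @param processed output of [process_fastq()] (or a compatible list with
#'   `reads` and `stats`).
#' @param blocklist named character vector of sequences, or a FASTA path.
#' @return the input list with matching reads removed and
#'   `stats$depleted` incremented by the number of removed read counts.
#' @export
deplete_sequences <- function(processed, blocklist) {
  if (is.character(blocklist) && length(blocklist) == 1 &&
      file.exists(blocklist)) {
    blocklist <- .read_fasta(blocklist)
  }
  reads <- processed$reads
  if (length(blocklist) == 0 || nrow(reads) == 0) {
    return(processed)
  }
  hits <- rep(FALSE, nrow(reads))
  for (b in blocklist) {
    m <- .exact_substring_hits(reads$sequence, b)
    hits <- hits | m
  }
  processed$stats$depleted <- processed$stats$depleted +
    sum(reads$count[hits])
  processed$reads <- reads[!hits, , drop = FALSE]
  rownames(processed$reads) <- NULL
  processed
}

# which query sequences occur as an exact substring of `subject`
.exact_substring_hits <- function(queries, subject) {
  found <- rep(FALSE, length(queries))
  subj <- Biostrings::DNAString(subject)
  for (w in unique(nchar(queries))) {
    sel <- which(nchar(queries) == w)
    if (w > nchar(subject)) next
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(queries[sel]))
    cnt <- Biostrings::countPDict(pd, subj)
    found[sel] <- cnt > 0
  }
  found
}

#' Read a count-encoded collapsed FASTA
#'
#' Inverse of [write_collapsed_fasta()]: parses `>seq{i}_x{count}` headers.
#'
#' @param path FASTA path.
#' @return data.frame with `sequence`, `count`.
#' @export
read_collapsed_fasta <- function(path) {
  seqs <- .read_fasta(path)
  counts <- suppressWarnings(as.integer(sub(".*_x", "", names(seqs))))
  if (anyNA(counts)) stop("headers are not in the seq{i}_x{count} dialect")
  data.frame(sequence = unname(seqs), count = counts,
             stringsAsFactors = FALSE)
}

#' Write collapsed reads as count-encoded FASTA
#'
#' Uses the `>seq{i}_x{count}` header dialect common to collapsed small-RNA
#' FASTA files.
#'
#' @param reads data.frame with `sequence`, `count`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  headers <- sprintf("seq%d_x%d", seq_len(nrow(reads)), reads$count)
  .write_fasta(stats::setNames(reads$sequence, headers), path)
}
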