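# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom Biostrings DNAStringSet reverseComplement
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.rand_dna <- function(n_bases) {
  paste(sample(c("A", "C", "G", "T"), n_bases, replace = TRUE), collapse = "")
}

# RNA-style (A/U/C/G) <-> DNA-style (A/T/C/G) tail alphabets; configs and
# reports use the RNA alphabet, reads are DNA.
.rna2dna <- function(x) chartr("U", "T", x)
.dna2rna <- function(x) chartr("T", "U", x)

# Vectorised substring extraction from a single genome string.
.substr_vec <- function(seq, start, end) {
  substring(seq, start, end)
}

#' Write a TSV with a provenance header block
#'
#' Stage outputs carry `# key: value` comment lines (package version, seed,
#' parameters actually used) followed by a plain tab-separated table, so every
#' intermediate is diff-able and individually re-loadable.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param meta named list of scalar provenance values.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(df, path, meta = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  meta <- c(list(package = "mirmzt", version = "0.1.0"), meta)
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, paste(meta[[k]], collapse = ",")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_stage_tsv()]
#'
#' @param path file path.
#' @return data.frame (header comments skipped).
#' @export
read_stage_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# Write a BED6 file from a GRanges (1-based closed -> 0-based half-open).
#' @importFrom GenomicRanges start end strand seqnames
.write_bed <- function(gr, path, name_col = "name", score = 0) {
  if (length(gr) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- if (name_col %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)[[name_col]])
  } else {
    paste0("feat", seq_along(gr))
  }
  str <- as.character(GenomicRanges::strand(gr))
  str[str == "*"] <- "."
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm, score = score, strand = str
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Read a BED6 file into a GRanges.  Tolerates empty files.
.read_bed <- function(path) {
  if (file.size(path) == 0) {
    return(GenomicRanges::GRanges())
  }
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  nm <- if (ncol(df) >= 4) df[[4]] else paste0("feat", seq_len(nrow(df)))
  str <- if (ncol(df) >= 6) ifelse(df[[6]] %in% c("+", "-"), df[[6]], "*") else "*"
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               strand = str)
  S4Vectors::mcols(gr)$name <- nm
  gr
}

.write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  out <- character(2L * length(seqs))
  out[c(TRUE, FALSE)] <- paste0(">", names(seqs))
  out[c(FALSE, TRUE)] <- unname(seqs)
  writeLines(out, path)
  invisible(path)
}

.read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
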