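# Synthetic-data module: FASTQ library simulation with a ground-truth sidecar.

.lib_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 2654435761 + as.numeric(idx) * 97003) %%
               2147483647)
}

# (d5, d3) templated-variant options for a 22-nt mature arm: up to 2 extra
# templated nt at the 5' end and -1..+5 at the 3' end, never the exact mature.
.noncanonical_options <- function() {
  opt <- expand.grid(d5 = 0:2, d3 = -1:5)
  opt[!(opt$d5 == 0 & opt$d3 == 0), ]
}

#' Simulate one small-RNA FASTQ library
#'
#' Per-miRNA read counts are drawn NB(mean = planted RPM x depth / 1e6,
#' dispersion = `config$nb_dispersion`) and split into canonical /
#' noncanonical (templated 5' or 3' variant) / NTA (3' non-templated tail)
#' isoforms by `config$isoform_fractions`; internal-mismatch decoy reads are
#' added at `config$frac_internal_mismatch`.  The remaining depth is filled
#' with background reads: structural RNAs (the 2S-rRNA-like locus gets a 25%
#' share), transposon reads (21 nt siRNA-sized, 22 nt, and >= 23 nt
#' piRNA-sized populations, drawn from either strand of identical genomic
#' copies), 21-nt cis-NAT reads from the antisense overlap, exonic, intronic
#' and intergenic reads.  Every raw read is insert + adapter + random filler
#' at `config$raw_read_length`, Q40 throughout except a configurable fraction
#' with one Q15 base inside the insert.
#'
#' One private RNG stream per library, seeded from (config seed, library
#' index), keeps libraries independent and byte-reproducible.
#'
#' @param bundle a `ReferenceBundle` from [generate_reference()].
#' @param config the [simulation_config()].
#' @param truth a [truth_table()] for `config`.
#' @param library_id a `library_id` present in `config$design`.
#' @param out_dir directory receiving `<library_id>.fastq` and
#'   `<library_id>.truth.tsv`.
#' @return list with `fastq`, `truth_path`, `truth` (data.frame), `n_reads`.
#' @export
simulate_library <- function(bundle, config, truth, library_id,
                             out_dir) {
  stopifnot(inherits(bundle, "ReferenceBundle"),
            inherits(config, "simulation_config"))
  idx <- match(library_id, config$design$library_id)
  if (is.na(idx)) stop("unknown design point: ", library_id)
  .preserve_rng(
    .simulate_library_impl(bundle, config, truth, idx, out_dir),
    .lib_seed(config$seed, idx)
  )
}

.simulate_library_impl <- function(bundle, config, truth, idx, out_dir) {
  dp <- config$design[idx, ]
  genome <- unname(bundle$genome)
  mirna <- bundle$mirna
  depth <- config$library_depth_mean

  prof <- truth$profiles
  prof <- prof[prof$genotype == dp$genotype & prof$timepoint == dp$timepoint, ]
  prof <- prof[match(mirna$mirna_id, prof$mirna_id), ]
  mu <- prof$mean_rpm * depth / 1e6
  counts <- stats::rnbinom(nrow(mirna), mu = mu, size = 1 / config$nb_dispersion)

  iso_names <- c("canonical", "noncanonical", "nta")
  ifrac <- config$isoform_fractions[iso_names]
  ifrac[is.na(ifrac)] <- 0
  opts <- .noncanonical_options()

  rows <- vector("list", nrow(mirna))
  for (i in seq_len(nrow(mirna))) {
    n <- counts[i]
    n_decoy <- stats::rbinom(1L, n, config$frac_internal_mismatch)
    if (n == 0 && n_decoy == 0) next
    split <- as.vector(stats::rmultinom(1L, n, ifrac))
    mat <- mirna$mature_seq[i]
    mat_len <- nchar(mat)
    out <- list()

    if (split[1] > 0) {
      out$canonical <- data.frame(insert = rep(mat, split[1]),
                                  isoform = "canonical", tail = "",
                                  tail_templated = NA,
                                  stringsAsFactors = FALSE)
    }
    if (split[2] > 0) {
      j <- sample.int(nrow(opts), split[2], replace = TRUE)
      seqs <- .substr_vec(genome, mirna$mat_start[i] - opts$d5[j],
                          mirna$mat_end[i] + opts$d3[j])
      out$noncanonical <- data.frame(insert = seqs, isoform = "noncanonical",
                                     tail = "", tail_templated = NA,
                                     stringsAsFactors = FALSE)
    }
    if (split[3] > 0) {
      tails <- .sample_tails(split[3], config,
                             template = substr(genome, mirna$mat_end[i] + 1L,
                                               mirna$mat_end[i] + 3L))
      out$nta <- data.frame(insert = paste0(mat, tails$dna),
                            isoform = "nta", tail = tails$rna,
                            tail_templated = tails$templated,
                            stringsAsFactors = FALSE)
    }
    if (n_decoy > 0) {
      pos <- sample(4:(mat_len - 4L), n_decoy, replace = TRUE)
      orig <- substring(mat, pos, pos)
      sub <- vapply(orig, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                             1L), character(1))
      ins <- vapply(seq_len(n_decoy), function(r) {
        paste0(substr(mat, 1, pos[r] - 1L), sub[r],
               substr(mat, pos[r] + 1L, mat_len))
      }, character(1))
      out$decoy <- data.frame(insert = ins, isoform = "decoy_internal",
                              tail = "", tail_templated = NA,
                              stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    df$source_class <- "mirna"
    df$source_id <- mirna$mirna_id[i]
    rows[[i]] <- df
  }
  mir_df <- do.call(rbind, rows)
  n_mir_reads <- if (is.null(mir_df)) 0L else nrow(mir_df)

  n_bg <- max(depth - n_mir_reads, 0L)
  bg_df <- .simulate_background(bundle, config, n_bg)

  reads <- rbind(mir_df, bg_df)
  n <- nrow(reads)
  reads$read_id <- sprintf("%s:%06d", dp$library_id, seq_len(n))
  reads$library_id <- dp$library_id

  # quality: Q40 everywhere, except one Q15 base inside the insert for a
  # small planted fraction (these must be removed by the quality filter)
  reads$low_quality <- stats::runif(n) < config$frac_low_quality
  lq_pos <- ifelse(reads$low_quality,
                   1L + floor(stats::runif(n) * nchar(reads$insert)), NA)

  raw_len <- config$raw_read_length
  fill_len <- pmax(raw_len - nchar(reads$insert) - nchar(config$adapter), 0L)
  pool <- .rand_dna(sum(fill_len) + 1L)
  ends <- cumsum(fill_len)
  fillers <- .substr_vec(pool, c(1L, ends[-n] + 1L), ends)
  raw <- substr(paste0(reads$insert, config$adapter, fillers), 1L, raw_len)
  qual <- strrep("I", nchar(raw))
  if (any(reads$low_quality)) {
    w <- which(reads$low_quality)
    qw <- qual[w]
    substr(qw, lq_pos[w], lq_pos[w]) <- "0"  # '0' = Q15 in phred+33
    qual[w] <- qw
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fastq <- file.path(out_dir, paste0(dp$library_id, ".fastq"))
  lines <- character(4L * n)
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- raw
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(lines, fastq)

  truth_df <- reads[, c("read_id", "library_id", "source_class", "source_id",
                        "isoform", "insert", "tail", "tail_templated",
                        "low_quality")]
  truth_path <- file.path(out_dir, paste0(dp$library_id, ".truth.tsv"))
  write_stage_tsv(truth_df, truth_path,
                  meta = list(library_id = dp$library_id,
                              seed = .lib_seed(config$seed, idx)))
  list(fastq = fastq, truth_path = truth_path, truth = truth_df, n_reads = n)
}

# Sample NTA tails for one miRNA.  `template` holds the 3 genomic bases just
# downstream of the mature 3' end.  With force_nontemplated, sampling is
# restricted (renormalized) to tail strings mismatching the template at every
# position, so the planted tail is guaranteed to be detectable as
# non-templated; the truth records per-tail templated-ness either way.
.sample_tails <- function(n, config, template) {
  freqs <- config$nta_tail_freqs
  rna <- names(freqs)
  dna <- .rna2dna(rna)
  tmpl <- strsplit(template, "")[[1]]
  templated <- vapply(dna, function(tl) {
    b <- strsplit(tl, "")[[1]]
    any(b == tmpl[seq_along(b)])
  }, logical(1))
  if (isTRUE(config$force_nontemplated)) {
    ok <- !templated
    if (!any(ok)) {
      alt <- setdiff(c("A", "C", "G", "T"), tmpl[1])[1]
      return(list(dna = rep(alt, n), rna = rep(.dna2rna(alt), n),
                  templated = rep(FALSE, n)))
    }
    pick <- sample(which(ok), n, replace = TRUE, prob = freqs[ok])
  } else {
    pick <- sample(seq_along(freqs), n, replace = TRUE, prob = freqs)
  }
  list(dna = dna[pick], rna = rna[pick], templated = unname(templated[pick]))
}

.simulate_background <- function(bundle, config, n_bg) {
  if (n_bg == 0) return(NULL)
  genome <- unname(bundle$genome)
  frac <- c(structural = 0, te = 0, cisnat = 0, exon = 0, intron = 0,
            intergenic = 0)
  frac[names(config$background_fractions)] <- config$background_fractions
  n_cls <- as.vector(stats::rmultinom(1L, n_bg, frac))
  names(n_cls) <- names(frac)
  pieces <- list()

  draw_from <- function(starts, ends, n, len_range = 20:28,
                        strands = NULL, fixed_len = NULL) {
    j <- sample.int(length(starts), n, replace = TRUE,
                    prob = ends - starts + 1)
    len <- if (is.null(fixed_len)) {
      sample(len_range, n, replace = TRUE)
    } else rep(fixed_len, n)
    len <- pmin(len, ends[j] - starts[j] + 1L)
    off <- floor(stats::runif(n) * (ends[j] - starts[j] + 2L - len))
    s <- starts[j] + off
    seqs <- .substr_vec(genome, s, s + len - 1L)
    if (!is.null(strands)) {
      minus <- stats::runif(n) < 0.5
      seqs[minus] <- .revcomp(seqs[minus])
    }
    list(seq = seqs, which = j)
  }

  st <- bundle$layers$structural
  if (n_cls["structural"] > 0) {
    n_st <- n_cls[["structural"]]
    is2s <- which(S4Vectors::mcols(st)$name == "rRNA_2S")
    w <- rep(0.75 / max(length(st) - 1L, 1L), length(st))
    w[is2s] <- 0.25
    j <- sample.int(length(st), n_st, replace = TRUE, prob = w)
    s0 <- GenomicRanges::start(st)[j]
    e0 <- GenomicRanges::end(st)[j]
    len <- sample(20:28, n_st, replace = TRUE)
    full <- j == is2s  # 2S reads are the exact locus sequence
    len[full] <- e0[full] - s0[full] + 1L
    len <- pmin(len, e0 - s0 + 1L)
    off <- floor(stats::runif(n_st) * (e0 - s0 + 2L - len))
    off[full] <- 0L
    seqs <- .substr_vec(genome, s0 + off, s0 + off + len - 1L)
    pieces$structural <- data.frame(
      insert = seqs, source_class = "structural",
      source_id = S4Vectors::mcols(st)$name[j], stringsAsFactors = FALSE)
  }

  te <- bundle$layers$te
  if (n_cls["te"] > 0) {
    n_te <- n_cls[["te"]]
    len <- sample(c(21L, 22L, 23:28), n_te, replace = TRUE,
                  prob = c(0.40, 0.10, rep(0.50 / 6, 6)))
    j <- sample.int(length(te), n_te, replace = TRUE)
    s0 <- GenomicRanges::start(te)[j]
    e0 <- GenomicRanges::end(te)[j]
    off <- floor(stats::runif(n_te) * (e0 - s0 + 2L - len))
    seqs <- .substr_vec(genome, s0 + off, s0 + off + len - 1L)
    minus <- stats::runif(n_te) < 0.5
    seqs[minus] <- .revcomp(seqs[minus])
    pieces$te <- data.frame(
      insert = seqs,
      source_class = ifelse(len == 21L, "te_sirna",
                            ifelse(len >= 23L, "te_pirna", "te_other")),
      source_id = S4Vectors::mcols(te)$name[j], stringsAsFactors = FALSE)
  }

  cn <- bundle$layers$cisnat
  if (n_cls["cisnat"] > 0) {
    n_cn <- n_cls[["cisnat"]]
    pairs <- unique(S4Vectors::mcols(cn)$pair)
    pj <- sample(pairs, n_cn, replace = TRUE)
    ov_s <- ov_e <- integer(n_cn)
    for (p in unique(pj)) {
      g <- cn[S4Vectors::mcols(cn)$pair == p]
      sel <- pj == p
      ov_s[sel] <- max(GenomicRanges::start(g))
      ov_e[sel] <- min(GenomicRanges::end(g))
    }
    off <- floor(stats::runif(n_cn) * (ov_e - ov_s + 2L - 21L))
    seqs <- .substr_vec(genome, ov_s + off, ov_s + off + 20L)
    minus <- stats::runif(n_cn) < 0.5
    seqs[minus] <- .revcomp(seqs[minus])
    pieces$cisnat <- data.frame(insert = seqs, source_class = "cisnat",
                                source_id = pj, stringsAsFactors = FALSE)
  }

  for (ly in c("exon", "intron")) {
    if (n_cls[ly] == 0) next
    g <- bundle$layers[[ly]]
    g <- g[S4Vectors::mcols(g)$name != "exon_mir_overlap"]
    d <- draw_from(GenomicRanges::start(g), GenomicRanges::end(g),
                   n_cls[[ly]])
    pieces[[ly]] <- data.frame(
      insert = d$seq, source_class = ly,
      source_id = S4Vectors::mcols(g)$name[d$which],
      stringsAsFactors = FALSE)
  }

  if (n_cls["intergenic"] > 0) {
    fr <- bundle$free
    d <- draw_from(GenomicRanges::start(fr), GenomicRanges::end(fr),
                   n_cls[["intergenic"]])
    pieces$intergenic <- data.frame(insert = d$seq,
                                    source_class = "intergenic",
                                    source_id = "intergenic",
                                    stringsAsFactors = FALSE)
  }

  bg <- do.call(rbind, pieces)
  bg$isoform <- NA_character_
  bg$tail <- ""
  bg$tail_templated <- NA
  rownames(bg) <- NULL
  bg[, c("insert", "isoform", "tail", "tail_templated", "source_class",
         "source_id")]
}

#' Simulate a full experiment
#'
#' Generates the reference bundle, the planted truth, and one FASTQ +
#' truth-sidecar pair per design row, plus a `manifest.tsv` tying libraries to
#' their design metadata and file paths.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory (reference under `ref/`, libraries under
#'   `fastq/`).
#' @return list with `config`, `bundle`, `truth`, `manifest` (data.frame).
#' @export
simulate_experiment <- function(config, out_dir) {
  bundle <- generate_reference(config, file.path(out_dir, "ref"))
  truth <- truth_table(config)
  fq_dir <- file.path(out_dir, "fastq")
  man <- config$design
  man$fastq <- NA_character_
  man$truth <- NA_character_
  for (i in seq_len(nrow(man))) {
    sim <- simulate_library(bundle, config, truth, man$library_id[i], fq_dir)
    man$fastq[i] <- sim$fastq
    man$truth[i] <- sim$truth_path
  }
  write_stage_tsv(man, file.path(out_dir, "manifest.tsv"),
                  meta = list(seed = config$seed))
  write_stage_tsv(truth$profiles, file.path(out_dir, "truth_profiles.tsv"),
                  meta = list(seed = config$seed))
  list(config = config, bundle = bundle, truth = truth, manifest = man)
}
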