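# Synthetic-data module: experiment configuration and planted ground truth.

#' Default 2 x 3 x 3 experimental design
#'
#' Two genotypes (wild type and a mutant in which zygotic miRNA synthesis
#' fails), three collection windows (0-2 h unfertilized eggs, 0-2 h embryos,
#' 2-4 h embryos), three biological replicates each: 18 libraries.
#'
#' @return data.frame with columns `library_id`, `genotype`, `timepoint`,
#'   `replicate`.
#' @export
default_design <- function() {
  d <- expand.grid(
    replicate = 1:3,
    timepoint = c("UF0_2h", "F0_2h", "F2_4h"),
    genotype = c("wt", "mut"),
    stringsAsFactors = FALSE
  )
  d <- d[, c("genotype", "timepoint", "replicate")]
  d$library_id <- sprintf("%s.%s.r%d", d$genotype, d$timepoint, d$replicate)
  d[, c("library_id", "genotype", "timepoint", "replicate")]
}

#' Planted mean expression profiles of the five miRNA classes
#'
#' Mean RPM per (class, genotype, timepoint).  Class semantics: A nonmaternal /
#' low zygotic, B low maternal / high zygotic, C high maternal / very high
#' zygotic, D low maternal / constant, E high maternal / constant.  In the
#' mutant, zygotic synthesis is suppressed or delayed, so classes A-C lose most
#' of their embryonic gain while D-E change little.
#'
#' @return data.frame with columns `class`, `genotype`, `timepoint`,
#'   `mean_rpm`.
#' @export
class_profiles <- function() {
  tp <- c("UF0_2h", "F0_2h", "F2_4h")
  wt <- rbind(
    A = c(1.4, 15, 72.6),
    B = c(23.7, 702, 5557),
    C = c(1301, 7821, 24042),
    D = c(46.1, 55, 71.9),
    E = c(1031, 1269, 1798)
  )
  mut <- rbind(
    A = c(1.2, 1.1, 2.1),
    B = c(23.9, 38.9, 320),
    C = c(1301, 2500, 5752),
    D = c(73.9, 28.1, 47.8),
    E = c(1502, 659, 1166)
  )
  long <- function(m, g) {
    data.frame(
      class = rep(rownames(m), times = 3),
      genotype = g,
      timepoint = rep(tp, each = 5),
      mean_rpm = as.vector(m),
      stringsAsFactors = FALSE
    )
  }
  rbind(long(wt, "wt"), long(mut, "mut"))
}

#' Build a validated simulation configuration
#'
#' Defaults state the simulated world: 5 expression classes x
#' `n_mirnas_per_class` miRNAs, a 200 kb toy genome, 18 libraries of
#' ~`library_depth_mean` reads with NB count noise, isoform mixture
#' canonical/noncanonical/NTA = 0.75/0.10/0.15, and mono/di-adenylation
#' dominated non-templated tails.
#'
#' @param n_mirnas_per_class miRNAs per expression class A-E.
#' @param n_te_families transposon consensus families (each inserted twice).
#' @param n_structural_loci structural-RNA loci (tRNA/rRNA/snoRNA/snRNA/ncRNA;
#'   always includes one 2S-rRNA-like locus).
#' @param n_cisnat_pairs overlapping antisense transcript pairs.
#' @param genome_length toy genome size in bases.
#' @param design library design data.frame (see [default_design()]).
#' @param library_depth_mean target raw reads per library.
#' @param nb_dispersion negative-binomial dispersion of planted counts.
#' @param isoform_fractions named probabilities for `canonical`,
#'   `noncanonical`, `nta`; must sum to 1.
#' @param nta_tail_freqs named probabilities over tail strings in the RNA
#'   alphabet (e.g. `A`, `AA`, `U`); must sum to 1, tail length 1-3.
#' @param adapter 3' adapter appended to every read.
#' @param raw_read_length raw sequencer read length (insert + adapter +
#'   random filler).
#' @param mirna_sigma_log2 per-miRNA abundance scatter (sd of a log2-normal
#'   multiplier applied to the class profile).
#' @param force_nontemplated if TRUE (default), planted NTA tails are
#'   guaranteed to mismatch the genomic template at every tail position, so
#'   tail detection has an unambiguous ground truth.
#' @param frac_low_quality fraction of reads given one Q15 base (exercises the
#'   quality filter).
#' @param frac_internal_mismatch per-miRNA fraction of extra decoy reads with
#'   one internal substitution (imperfect genome match that is not a tail).
#' @param background_fractions named proportions of non-miRNA reads over
#'   `structural`, `te`, `cisnat`, `exon`, `intron`, `intergenic`.
#' @param seed master RNG seed.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_mirnas_per_class = 10,
                              n_te_families = 4,
                              n_structural_loci = 8,
                              n_cisnat_pairs = 3,
                              genome_length = 200000,
                              design = default_design(),
                              library_depth_mean = 5e4,
                              nb_dispersion = 0.1,
                              isoform_fractions = c(canonical = 0.75,
                                                    noncanonical = 0.10,
                                                    nta = 0.15),
                              nta_tail_freqs = c(A = 0.49, AA = 0.20,
                                                 U = 0.12, AAA = 0.08,
                                                 C = 0.06, G = 0.02,
                                                 UU = 0.03),
                              adapter = "TGGAATTCTCGG",
                              raw_read_length = 50,
                              mirna_sigma_log2 = 0.5,
                              force_nontemplated = TRUE,
                              frac_low_quality = 0.01,
                              frac_internal_mismatch = 0.01,
                              background_fractions = c(structural = 0.55,
                                                       te = 0.20,
                                                       cisnat = 0.05,
                                                       exon = 0.06,
                                                       intron = 0.04,
                                                       intergenic = 0.10),
                              seed = 1L) {
  stopifnot(
    n_mirnas_per_class > 0, n_te_families > 0, n_structural_loci > 0,
    n_cisnat_pairs > 0, genome_length > 0, library_depth_mean > 0,
    nb_dispersion > 0, nchar(adapter) > 0
  )
  if (abs(sum(isoform_fractions) - 1) > 1e-9) {
    stop("isoform_fractions must sum to 1")
  }
  if (abs(sum(nta_tail_freqs) - 1) > 1e-9) {
    stop("nta_tail_freqs must sum to 1")
  }
  if (!all(names(isoform_fractions) %in%
           c("canonical", "noncanonical", "nta"))) {
    stop("isoform_fractions names must be canonical/noncanonical/nta")
  }
  if (!all(nchar(names(nta_tail_freqs)) %in% 1:3) ||
      !all(grepl("^[AUCG]+$", names(nta_tail_freqs)))) {
    stop("nta_tail_freqs names must be 1-3 nt strings over A/U/C/G")
  }
  req <- c("library_id", "genotype", "timepoint", "replicate")
  stopifnot(all(req %in% names(design)))
  stopifnot(all(design$genotype %in% c("wt", "mut")),
            all(design$timepoint %in% c("UF0_2h", "F0_2h", "F2_4h")))
  cfg <- list(
    n_mirnas_per_class = as.integer(n_mirnas_per_class),
    n_te_families = as.integer(n_te_families),
    n_structural_loci = as.integer(n_structural_loci),
    n_cisnat_pairs = as.integer(n_cisnat_pairs),
    genome_length = as.integer(genome_length),
    design = design,
    library_depth_mean = library_depth_mean,
    nb_dispersion = nb_dispersion,
    isoform_fractions = isoform_fractions,
    nta_tail_freqs = nta_tail_freqs,
    adapter = adapter,
    raw_read_length = as.integer(raw_read_length),
    mirna_sigma_log2 = mirna_sigma_log2,
    force_nontemplated = force_nontemplated,
    frac_low_quality = frac_low_quality,
    frac_internal_mismatch = frac_internal_mismatch,
    background_fractions = background_fractions,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  cfg
}

#' Planted per-miRNA expression truth
#'
#' Assigns each simulated miRNA a class label (A-E) and an expected RPM per
#' (genotype, timepoint): the class mean profile scaled by a per-miRNA
#' log2-normal multiplier (drawn once under the master seed, so the truth is a
#' deterministic function of the configuration).
#'
#' @param config a [simulation_config()].
#' @return list with `mirnas` (mirna_id, class, multiplier) and `profiles`
#'   (mirna_id, class, genotype, timepoint, mean_rpm).
#' @export
truth_table <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_mirnas_per_class
  classes <- rep(c("A", "B", "C", "D", "E"), each = n)
  ids <- sprintf("mir-%03d", seq_along(classes))
  rng <- .local_rng(config$seed, 7L)
  mult <- 2^(rng$norm(length(ids), sd = config$mirna_sigma_log2))
  mirnas <- data.frame(mirna_id = ids, class = classes,
                       multiplier = mult, stringsAsFactors = FALSE)
  prof <- class_profiles()
  profiles <- merge(mirnas, prof, by = "class", sort = FALSE)
  profiles$mean_rpm <- profiles$mean_rpm * profiles$multiplier
  profiles <- profiles[order(profiles$mirna_id, profiles$genotype,
                             profiles$timepoint),
                       c("mirna_id", "class", "genotype", "timepoint",
                         "mean_rpm")]
  rownames(profiles) <- NULL
  list(mirnas = mirnas, profiles = profiles)
}

# A tiny self-contained RNG wrapper: runs under a private .Random.seed so the
# global stream is untouched, seeded by a 32-bit hash of (seed, stream).
.local_rng <- function(seed, stream) {
  mix <- (as.numeric(seed) * 2654435761 + as.numeric(stream) * 40503) %%
    2147483647
  env <- new.env()
  env$seed <- as.integer(mix)
  with_rng <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      })
      if (is.null(env$state)) {
        set.seed(env$seed)
      } else {
        assign(".Random.seed", env$state, globalenv())
      }
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      out
    }
  }
  list(
    norm = with_rng(function(n, sd = 1) stats::rnorm(n, sd = sd)),
    unif_int = with_rng(function(n, lo, hi) {
      lo + floor(stats::runif(n) * (hi - lo + 1))
    }),
    nbinom = with_rng(function(n, mu, size) stats::rnbinom(n, mu = mu,
                                                           size = size)),
    sample = with_rng(function(x, size, replace = FALSE, prob = NULL) {
      sample(x, size, replace = replace, prob = prob)
    }),
    runif = with_rng(function(n) stats::runif(n))
  )
}
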