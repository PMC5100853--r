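# Profiles module: sample-set aggregation, hierarchical clustering into
# expression classes, class summaries, and subset-selection filters.

.SAMPLE_SETS <- expand.grid(
  timepoint = c("UF0_2h", "F0_2h", "F2_4h"),
  genotype = c("wt", "mut"), stringsAsFactors = FALSE
)[, c("genotype", "timepoint")]

.set_names <- function(sets = .SAMPLE_SETS) {
  sprintf("%s.%s", sets$genotype, sets$timepoint)
}

#' Mean RPM per sample set
#'
#' Arithmetic mean over the replicate libraries of each (genotype,
#' timepoint) sample set; the design must be complete (every set present
#' with the same number of replicates).
#'
#' @param rpm_mat features x libraries RPM matrix.
#' @param design design data.frame (`library_id`, `genotype`, `timepoint`)
#'   covering the matrix columns.
#' @return features x 6 matrix, columns `wt.UF0_2h` ... `mut.F2_4h`.
#' @export
sample_set_means <- function(rpm_mat, design) {
  sets <- .SAMPLE_SETS
  nm <- .set_names(sets)
  reps <- integer(nrow(sets))
  out <- matrix(NA_real_, nrow(rpm_mat), nrow(sets),
                dimnames = list(rownames(rpm_mat), nm))
  for (i in seq_len(nrow(sets))) {
    libs <- design$library_id[design$genotype == sets$genotype[i] &
                                design$timepoint == sets$timepoint[i]]
    libs <- intersect(libs, colnames(rpm_mat))
    reps[i] <- length(libs)
    if (length(libs)) {
      out[, i] <- rowMeans(rpm_mat[, libs, drop = FALSE])
    }
  }
  if (length(unique(reps)) != 1 || reps[1] == 0) {
    stop("incomplete design: every sample set needs the same number of replicates")
  }
  out
}

#' Select canonical miRNAs for expression clustering
#'
#' Keeps features whose mean RPM is `>= min_rpm` (inclusive) in at least one
#' of the six sample sets.
#'
#' @param set_means [sample_set_means()] output.
#' @param min_rpm inclusive threshold (default 10).
#' @return character vector of kept feature names.
#' @export
select_canonical_for_clustering <- function(set_means, min_rpm = 10) {
  rownames(set_means)[apply(set_means, 1, max) >= min_rpm]
}

#' Hierarchical clustering of expression profiles into classes
#'
#' Profiles are log2(mean RPM + 1) over the three wild-type sample sets
#' (classes are defined by wild-type developmental behavior; mutant columns
#' are summarized per class afterwards).  Agglomerative clustering with
#' Euclidean distance and complete linkage, tree cut at `k`; clusters are
#' relabeled A, B, ... by ascending wild-type unfertilized-egg mean and,
#' within ties, descending zygotic gain (wt 2-4 h / wt UF ratio), giving a
#' reproducible mapping onto the class semantics.
#'
#' Ward linkage (`ward.D2`) is the default: on planted-profile benchmarks it
#' recovers well-separated classes reliably where complete linkage's
#' max-distance criterion fragments low-abundance classes; any [stats::hclust()]
#' linkage can be requested instead.
#'
#' @param set_means [sample_set_means()] matrix restricted to the features
#'   to cluster.
#' @param k number of classes (default 5).
#' @param columns which columns to cluster on (default the wild-type sets).
#' @param method,distance linkage and distance (defaults ward.D2/euclidean).
#' @return list with `classes` (named character vector of labels),
#'   `order` (cluster relabeling), `hclust` (the tree).
#' @export
cluster_classes <- function(set_means, k = 5,
                            columns = c("wt.UF0_2h", "wt.F0_2h",
                                        "wt.F2_4h"),
                            method = "ward.D2", distance = "euclidean") {
  stopifnot(all(columns %in% colnames(set_means)))
  if (nrow(set_means) < k) stop("k exceeds the number of features")
  lg <- log2(set_means[, columns, drop = FALSE] + 1)
  hc <- stats::hclust(stats::dist(lg, method = distance), method = method)
  cut <- stats::cutree(hc, k = k)

  uf <- tapply(set_means[, columns[1]], cut, mean)
  gain <- tapply((set_means[, columns[length(columns)]] + 1) /
                   (set_means[, columns[1]] + 1), cut, mean)
  ord <- order(uf, -gain)
  labels <- stats::setNames(LETTERS[seq_len(k)], as.character(ord))
  classes <- stats::setNames(unname(labels[as.character(cut)]),
                             rownames(set_means))
  list(classes = classes, order = labels, hclust = hc)
}

#' Per-class per-sample-set mean expression
#'
#' @param classes named class labels from [cluster_classes()].
#' @param set_means full 6-column [sample_set_means()] matrix.
#' @param levels class labels to report (defaults to those observed);
#'   levels with no members are reported with `n = 0` and NA means.
#' @return data.frame: `class`, `n`, one mean-RPM column per sample set.
#' @export
class_summary <- function(classes, set_means,
                          levels = sort(unique(unname(classes)))) {
  lv <- levels
  out <- data.frame(class = lv, n = 0L, stringsAsFactors = FALSE)
  means <- matrix(NA_real_, length(lv), ncol(set_means),
                  dimnames = list(lv, colnames(set_means)))
  for (cl in lv) {
    members <- names(classes)[classes == cl]
    members <- intersect(members, rownames(set_means))
    out$n[out$class == cl] <- length(members)
    if (length(members)) {
      means[cl, ] <- colMeans(set_means[members, , drop = FALSE])
    }
  }
  cbind(out, as.data.frame(means))
}

#' Select canonical miRNAs downregulated in the mutant
#'
#' Union over the two embryonic contrasts of features with FDR <= `max_fdr`
#' and negative log fold-change (mutant below wild type), intersected with
#' features reaching `min_rpm` mean RPM in at least one sample set.
#'
#' @param de_list list of [nb_glm_lrt()] results (one per embryo timepoint
#'   contrast, mutant vs wild type).
#' @param set_means canonical [sample_set_means()] matrix.
#' @param max_fdr FDR cutoff (default 0.05).
#' @param min_rpm sample-set mean RPM threshold (default 10, inclusive).
#' @return character vector of selected miRNA ids.
#' @export
select_downregulated_mirnas <- function(de_list, set_means,
                                        max_fdr = 0.05, min_rpm = 10) {
  hit <- character(0)
  for (de in de_list) {
    sel <- !is.na(de$FDR) & de$FDR <= max_fdr & de$logFC < 0
    hit <- union(hit, de$feature[sel])
  }
  expressed <- select_canonical_for_clustering(set_means, min_rpm)
  sort(intersect(hit, expressed))
}

# shared machinery for the isoform-subset filters: per-miRNA 6-set RPM of
# the three isoform types
.isoform_set_arrays <- function(iso_set_means) {
  stopifnot(all(c("canonical", "noncanonical", "nta") %in%
                  names(iso_set_means)))
  tot <- iso_set_means$canonical + iso_set_means$noncanonical +
    iso_set_means$nta
  list(total = tot,
       canonical = iso_set_means$canonical,
       noncanonical = iso_set_means$noncanonical,
       nta = iso_set_means$nta)
}

.wt_cols <- function(m) {
  list(eggs = m[, "wt.UF0_2h"],
       embryos = rowMeans(m[, c("wt.F0_2h", "wt.F2_4h"), drop = FALSE]))
}

#' Select miRNAs with a prominent, dynamic noncanonical isoform
#'
#' Criteria (per miRNA, over the six sample sets): (1) total isoform RPM
#' >= 10 in at least one set; (2) noncanonical share of the total >= 0.5 in
#' at least one set; (3) the noncanonical share differs by >= 0.2 between
#' wild-type eggs and wild-type embryos (shares, not RPM: the thresholds are
#' on the proportion scale).
#'
#' @param iso_set_means list of three features x 6-set mean-RPM matrices
#'   named `canonical`, `noncanonical`, `nta`.
#' @return data.frame with per-criterion pass flags and a `selected` column.
#' @export
select_noncanonical_subset <- function(iso_set_means) {
  a <- .isoform_set_arrays(iso_set_means)
  share <- a$noncanonical / pmax(a$total, .Machine$double.eps)
  c1 <- apply(a$total, 1, max) >= 10
  c2 <- apply(share, 1, max) >= 0.5
  wt <- .wt_cols(share)
  c3 <- abs(wt$eggs - wt$embryos) >= 0.2
  data.frame(mirna_id = rownames(a$total), crit_total = c1,
             crit_share = c2, crit_dynamic = c3,
             selected = c1 & c2 & c3, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Select miRNAs with a prominent, dynamic NTA isoform
#'
#' Criteria: (1) total isoform RPM >= 10 in at least one set; (2) NTA share
#' of the total >= 0.2 in TWO or more sets; (3) NTA share differs by >= 0.1
#' between wild-type eggs and embryos, or by >= 0.2 between wild-type and
#' mutant embryos (proportion scale).
#'
#' @inheritParams select_noncanonical_subset
#' @return data.frame with per-criterion pass flags and a `selected` column.
#' @export
select_nta_subset <- function(iso_set_means) {
  a <- .isoform_set_arrays(iso_set_means)
  share <- a$nta / pmax(a$total, .Machine$double.eps)
  c1 <- apply(a$total, 1, max) >= 10
  c2 <- rowSums(share >= 0.2) >= 2
  wt <- .wt_cols(share)
  mut_embryos <- rowMeans(share[, c("mut.F0_2h", "mut.F2_4h"),
                                drop = FALSE])
  c3 <- abs(wt$eggs - wt$embryos) >= 0.1 |
    abs(wt$embryos - mut_embryos) >= 0.2
  data.frame(mirna_id = rownames(a$total), crit_total = c1,
             crit_share = c2, crit_dynamic = c3,
             selected = c1 & c2 & c3, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Adjusted Rand Index between two partitions
#'
#' @param a,b equal-length label vectors.
#' @return ARI in `[-1, 1]`; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(length(a))
  expected <- sum_a * sum_b / n
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
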