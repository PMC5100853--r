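# Overlap-stats module: gene lists, target-set assembly, one-tailed Fisher
# (hypergeometric) overlap tests with odds ratios.

#' Construct a validated gene list
#'
#' @param name list name.
#' @param members character identifiers (whitespace-stripped, deduplicated;
#'   comparison is case-sensitive).
#' @param universe optional universe of identifiers; members must be a
#'   subset when given.
#' @return a `GeneList` list.
#' @export
gene_list <- function(name, members, universe = NULL) {
  members <- unique(trimws(members))
  members <- members[nzchar(members)]
  if (!is.null(universe)) {
    universe <- unique(trimws(universe))
    extra <- setdiff(members, universe)
    if (length(extra)) {
      stop(sprintf("gene list '%s': %d members outside the universe",
                   name, length(extra)))
    }
  }
  structure(list(name = name, members = members, universe = universe),
            class = "GeneList")
}

#' Read a gene list from a text file
#'
#' Accepts one-identifier-per-line files or TSVs whose first column holds
#' the identifiers (a header row is auto-detected via a `gene` prefix).
#'
#' @param path file path.
#' @param name list name (defaults to the file base name).
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, name = NULL) {
  lines <- readLines(path)
  ids <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  ids <- ids[nzchar(ids)]
  if (length(ids) && grepl("^gene", ids[1], ignore.case = TRUE)) {
    ids <- ids[-1]
  }
  gene_list(name %||% sub("\\.[^.]*$", "", basename(path)), ids)
}

#' Assemble the target gene set of a miRNA list
#'
#' From a TargetScan-like table (`gene_id`, `mirna_family`, `site_region`
#' in ORF/3UTR, logical/0-1 `conserved`), collects genes having at least one
#' conserved ORF or 3'UTR site for at least one miRNA in `mirna_list`.
#' miRNAs absent from the table contribute nothing (their ids are recorded
#' in the `missing_mirnas` attribute).
#'
#' @param target_table data.frame or TSV path.
#' @param mirna_list character miRNA ids.
#' @param name name for the resulting gene list.
#' @return a [gene_list()] of target genes.
#' @export
build_target_set <- function(target_table, mirna_list,
                             name = "mirna_targets") {
  if (is.character(target_table)) {
    target_table <- read_stage_tsv(target_table)
  }
  req <- c("gene_id", "mirna_family", "site_region", "conserved")
  stopifnot(all(req %in% names(target_table)))
  present <- intersect(mirna_list, unique(target_table$mirna_family))
  missing <- setdiff(mirna_list, present)
  sel <- target_table$mirna_family %in% present &
    as.logical(target_table$conserved) &
    target_table$site_region %in% c("ORF", "3UTR")
  gl <- gene_list(name, unique(target_table$gene_id[sel]))
  attr(gl, "missing_mirnas") <- missing
  gl
}

#' One-tailed Fisher (hypergeometric) overlap test
#'
#' Builds the 2x2 contingency table from a universe of size `n_universe`,
#' two list sizes and their intersection: `a` = overlap, `b` = |A| - a,
#' `c` = |B| - a, `d` = the remainder.  The sample odds ratio is
#' `(a d)/(b c)` (infinite when `b c` = 0) and the one-tailed p-value is the
#' upper-tail hypergeometric probability `P(X >= a)`.  The conditional-MLE
#' odds ratio from [stats::fisher.test()] is also reported.
#'
#' @param n_universe universe size.
#' @param list_a,list_b either character vectors of identifiers or integer
#'   sizes (in which case `overlap` must be given).
#' @param overlap intersection size when sizes are passed directly.
#' @param cmle also compute the conditional-MLE odds ratio (slower; uses
#'   [stats::fisher.test()]).
#' @return an `OverlapResult`: list with `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `odds_ratio_cmle` (NA unless `cmle = TRUE`), `p_one_tailed`.
#' @export
fisher_overlap <- function(n_universe, list_a, list_b, overlap = NULL,
                           cmle = FALSE) {
  if (is.character(list_a) || is.character(list_b)) {
    stopifnot(is.character(list_a), is.character(list_b))
    list_a <- unique(list_a)
    list_b <- unique(list_b)
    overlap <- length(intersect(list_a, list_b))
    list_a <- length(list_a)
    list_b <- length(list_b)
  }
  stopifnot(!is.null(overlap), overlap <= min(list_a, list_b),
            list_a <= n_universe, list_b <= n_universe)
  a <- overlap
  b <- list_a - a
  cc <- list_b - a
  d <- n_universe - a - b - cc
  if (d < 0) stop("inconsistent inputs: universe smaller than the union")
  or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
  p <- stats::phyper(a - 1, list_a, n_universe - list_a, list_b,
                     lower.tail = FALSE)
  or_cmle <- if (isTRUE(cmle)) {
    unname(stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                              alternative = "greater")$estimate)
  } else {
    NA_real_
  }
  structure(list(a = a, b = b, c = cc, d = d,
                 odds_ratio = or,
                 odds_ratio_cmle = or_cmle,
                 p_one_tailed = p),
            class = "OverlapResult")
}

#' Tabulated overlap report for a set of comparisons
#'
#' @param comparisons list of lists, each with `name`, `n_universe`,
#'   `list_a`, `list_b` and optionally `overlap` (as in [fisher_overlap()]).
#' @return data.frame with dataset sizes, overlap, one-tailed p and odds
#'   ratio per comparison (Table-style layout).
#' @export
overlap_report <- function(comparisons) {
  rows <- lapply(comparisons, function(cmp) {
    res <- fisher_overlap(cmp$n_universe, cmp$list_a, cmp$list_b,
                          cmp$overlap %||% NULL)
    size_a <- if (is.character(cmp$list_a)) {
      length(unique(cmp$list_a))
    } else cmp$list_a
    size_b <- if (is.character(cmp$list_b)) {
      length(unique(cmp$list_b))
    } else cmp$list_b
    data.frame(dataset = cmp$name, universe = cmp$n_universe,
               n_a = size_a, n_b = size_b, overlap = res$a,
               p_value = res$p_one_tailed, odds_ratio = res$odds_ratio,
               stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    return(data.frame(dataset = character(0), universe = integer(0),
                      n_a = integer(0), n_b = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      odds_ratio = numeric(0)))
  }
  do.call(rbind, rows)
}
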