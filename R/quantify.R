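# Quantify module: RPM, expression filtering, TMM normalization, NB-GLM
# likelihood-ratio differential expression, BH FDR.

#' Reads-per-million normalization
#'
#' @param counts features x libraries matrix of (weighted) counts.
#' @param lib_sizes per-library total mapped weighted reads; defaults to
#'   column sums.
#' @return RPM matrix: `count / lib_size * 1e6`.
#' @export
rpm <- function(counts, lib_sizes = colSums(counts)) {
  stopifnot(all(lib_sizes > 0), length(lib_sizes) == ncol(counts))
  sweep(counts, 2, lib_sizes, "/") * 1e6
}

#' Expression filter: RPM above a cutoff in enough libraries
#'
#' Keeps features with RPM strictly greater than `min_rpm` in at least
#' `min_libraries` libraries (defaults: > 1 RPM in >= 6 of the 18 libraries).
#'
#' @param rpm_mat RPM matrix.
#' @param min_rpm strict lower bound.
#' @param min_libraries minimum number of libraries exceeding it.
#' @return character vector of kept feature names (row names).
#' @export
filter_expressed <- function(rpm_mat, min_rpm = 1, min_libraries = 6) {
  keep <- rowSums(rpm_mat > min_rpm) >= min_libraries
  rownames(rpm_mat)[keep]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference library is the one whose 75th
#' percentile of library-size-scaled counts is closest to the mean of those
#' percentiles; for each library, M (log2 ratio vs reference) and A (mean
#' log2 abundance) are computed over features nonzero in both libraries, the
#' 30% most extreme M and 5% most extreme A values are trimmed on each side,
#' and the factor is 2 to the inverse-asymptotic-variance weighted mean of
#' the surviving M values.  Factors are rescaled to geometric mean 1.
#'
#' @param counts features x libraries count matrix.
#' @param lib_sizes library sizes (default column sums).
#' @param logratio_trim,sum_trim per-side trim fractions for M and A.
#' @return named numeric vector of normalization factors.
#' @export
tmm_factors <- function(counts, lib_sizes = colSums(counts),
                        logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least two libraries")
  if (any(lib_sizes <= 0) || any(colSums(counts) == 0)) {
    stop("library with all-zero counts")
  }
  f75 <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j] / lib_sizes[j], 0.75)
  }, numeric(1))
  # guard: with identical scaled profiles any reference gives the same answer
  ref <- which.min(abs(f75 - mean(f75)))

  one_factor <- function(k) {
    y_k <- counts[, k]
    y_r <- counts[, ref]
    n_k <- lib_sizes[k]
    n_r <- lib_sizes[ref]
    fin <- y_k > 0 & y_r > 0
    y_k <- y_k[fin]; y_r <- y_r[fin]
    if (!length(y_k)) return(1)
    m <- log2((y_k / n_k) / (y_r / n_r))
    a <- 0.5 * log2((y_k / n_k) * (y_r / n_r))
    v <- (n_k - y_k) / (n_k * y_k) + (n_r - y_r) / (n_r * y_r)
    if (max(abs(m)) < 1e-6) return(1)
    nn <- length(m)
    lo_m <- floor(nn * logratio_trim) + 1
    hi_m <- nn + 1 - lo_m
    lo_a <- floor(nn * sum_trim) + 1
    hi_a <- nn + 1 - lo_a
    rm <- rank(m); ra <- rank(a)
    keep <- rm >= lo_m & rm <= hi_m & ra >= lo_a & ra <= hi_a
    if (!any(keep)) return(1)
    f <- sum(m[keep] / v[keep]) / sum(1 / v[keep])
    if (!is.finite(f)) f <- 0
    2^f
  }
  fac <- vapply(seq_len(ncol(counts)), one_factor, numeric(1))
  fac <- fac / exp(mean(log(fac)))
  names(fac) <- colnames(counts)
  fac
}

# ---- NB GLM ----------------------------------------------------------------

.nb_loglik <- function(y, mu, phi) {
  if (phi <= 0) {
    sum(stats::dpois(y, mu, log = TRUE))
  } else {
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  }
}

# IRLS fit of an NB log-linear model with offsets at fixed dispersion.
.nb_fit <- function(y, X, offset, phi, maxit = 50L, tol = 1e-8) {
  p <- ncol(X)
  beta <- tryCatch(qr.solve(X, log(y + 0.5) - offset),
                   error = function(e) rep(0, p))
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + phi * mu)
    z <- (eta - offset) + (y - mu) / mu
    fit <- tryCatch({
      xw <- X * w
      solve(crossprod(xw, X), crossprod(xw, z))
    }, error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- drop(fit)
    ll <- .nb_loglik(y, exp(pmin(pmax(drop(X %*% beta_new) + offset,
                                      -30), 30)), phi)
    if (!is.finite(ll)) break
    if (abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      beta <- beta_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    ll_old <- ll
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  list(beta = beta, mu = mu, loglik = .nb_loglik(y, mu, phi),
       converged = converged || maxit == 0L)
}

#' Estimate a common NB dispersion across features
#'
#' Pseudo-likelihood (Pearson) estimator: the dispersion solving
#' `sum (y - mu)^2 / (mu (1 + phi mu)) = total residual df`, with the
#' per-feature means refit between iterations.  This moment-style estimator
#' is approximately unbiased for the residual degrees of freedom, which a raw
#' profile likelihood is not.
#'
#' @param counts features x libraries matrix.
#' @param X design matrix (full model).
#' @param offset per-library log offsets (log lib size + log TMM factor).
#' @param iterations refit rounds.
#' @return scalar dispersion (>= 0).
#' @export
estimate_common_dispersion <- function(counts, X, offset,
                                       iterations = 3L) {
  counts <- as.matrix(counts)
  df_resid <- (ncol(counts) - qr(X)$rank) * nrow(counts)
  stopifnot(df_resid > 0)
  phi <- 0.1
  for (it in seq_len(iterations)) {
    mus <- t(apply(counts, 1, function(y) .nb_fit(y, X, offset, phi)$mu))
    pearson_gap <- function(ph) {
      sum((counts - mus)^2 / (mus * (1 + ph * mus))) - df_resid
    }
    if (pearson_gap(0) <= 0) {
      phi_new <- 0
    } else if (pearson_gap(10) >= 0) {
      phi_new <- 10
    } else {
      phi_new <- stats::uniroot(pearson_gap, c(0, 10), tol = 1e-6)$root
    }
    if (abs(phi_new - phi) < 1e-4) {
      phi <- phi_new
      break
    }
    phi <- phi_new
  }
  phi
}

#' NB-GLM likelihood-ratio test between two group levels
#'
#' Fits, per feature, a negative-binomial log-linear model with one mean per
#' group (cell-means parameterization) and offsets
#' `log(lib_size x TMM factor)`, and compares it by likelihood ratio against
#' a reduced model in which the two contrasted groups share a mean.  The LRT
#' statistic is referred to a chi-square with 1 df.  A common dispersion is
#' estimated from the data unless supplied.
#'
#' @param counts features x libraries matrix.
#' @param group factor/character of library group labels (e.g.
#'   `genotype.timepoint`).
#' @param contrast length-2 character: `c(test_level, reference_level)`;
#'   logFC is log2(test / reference).
#' @param lib_sizes library sizes (default column sums).
#' @param norm_factors TMM factors (default all 1).
#' @param dispersion common NB dispersion; estimated when NULL.
#' @return data.frame: `feature`, `logFC`, `LRT`, `PValue`, `FDR` (BH over
#'   converged features), plus the dispersion used as an attribute.
#' @export
nb_glm_lrt <- function(counts, group, contrast,
                       lib_sizes = colSums(counts),
                       norm_factors = NULL, dispersion = NULL) {
  counts <- as.matrix(counts)
  group <- factor(group)
  stopifnot(length(group) == ncol(counts), length(contrast) == 2,
            all(contrast %in% levels(group)))
  if (is.null(norm_factors)) norm_factors <- rep(1, ncol(counts))
  offset <- log(lib_sizes * norm_factors)

  X_full <- stats::model.matrix(~ 0 + group)
  colnames(X_full) <- levels(group)
  merged <- as.character(group)
  merged[merged %in% contrast] <- "merged."
  merged <- factor(merged)
  X_red <- if (nlevels(merged) == 1) {
    matrix(1, ncol(counts), 1)
  } else {
    stats::model.matrix(~ 0 + merged)
  }

  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(counts, X_full, offset)
  }

  nfeat <- nrow(counts)
  logfc <- lrt <- pval <- rep(NA_real_, nfeat)
  for (i in seq_len(nfeat)) {
    y <- counts[i, ]
    full <- .nb_fit(y, X_full, offset, dispersion)
    red <- .nb_fit(y, X_red, offset, dispersion)
    if (!full$converged || !red$converged) next
    stat <- max(2 * (full$loglik - red$loglik), 0)
    lrt[i] <- stat
    pval[i] <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    logfc[i] <- (full$beta[match(contrast[1], colnames(X_full))] -
                   full$beta[match(contrast[2], colnames(X_full))]) / log(2)
  }
  res <- data.frame(
    feature = rownames(counts) %||% as.character(seq_len(nfeat)),
    logFC = logfc, LRT = lrt, PValue = pval,
    FDR = bh_fdr(pval), stringsAsFactors = FALSE)
  attr(res, "dispersion") <- dispersion
  res
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p p-values in `[0, 1]`; NAs are passed through and excluded from
#'   the adjustment.
#' @return adjusted values, monotone nondecreasing in p-rank.
#' @export
bh_fdr <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  pv <- p[ok]
  stopifnot(all(pv >= 0 & pv <= 1))
  m <- length(pv)
  o <- order(pv, decreasing = TRUE)
  adj <- pmin(1, cummin(pv[o] * m / seq(m, 1)))
  out[ok[o]] <- adj
  out
}
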