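# profiles module: aggregation, clustering, class summaries, subset filters.

mk_design <- function() default_design()

rand_set_means <- function(n, seed) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n * 6, 1 / 20), n, 6)
    dimnames(m) <- list(sprintf("mir-%02d", seq_len(n)),
                        c("wt.UF0_2h", "wt.F0_2h", "wt.F2_4h",
                          "mut.UF0_2h", "mut.F0_2h", "mut.F2_4h"))
    m
  })
}

test_that("sample_set_means equals a brute-force group-by and errors when incomplete", {
  des <- mk_design()
  set.seed(41)
  m <- matrix(rexp(10 * 18), 10, 18,
              dimnames = list(paste0("f", 1:10), des$library_id))
  got <- sample_set_means(m, des)
  expect_equal(got["f1", "wt.F0_2h"],
               mean(m["f1", c("wt.F0_2h.r1", "wt.F0_2h.r2", "wt.F0_2h.r3")]))
  for (s in colnames(got)) {
    libs <- paste0(s, ".r", 1:3)
    expect_equal(got[, s], rowMeans(m[, libs]))
  }
  expect_equal(unname(got[2, "mut.F2_4h"]),
               mean(c(m[2, "mut.F2_4h.r1"], m[2, "mut.F2_4h.r2"],
                      m[2, "mut.F2_4h.r3"])))
  expect_error(sample_set_means(m[, 1:17], des[1:17, ]), "incomplete")
})

test_that("clustering threshold is inclusive at 10 and drops 9.9", {
  m <- rand_set_means(4, 42)
  m[1, ] <- 0; m[1, 2] <- 10.0
  m[2, ] <- 0; m[2, 3] <- 9.9
  keep <- select_canonical_for_clustering(m)
  expect_true(rownames(m)[1] %in% keep)
  expect_false(rownames(m)[2] %in% keep)
})

test_that("cluster_classes: duplicates cluster together, k=1 and k>n behave", {
  m <- rand_set_means(12, 43)
  m[2, ] <- m[1, ]  # exact duplicate
  cl <- cluster_classes(m, k = 4)
  expect_equal(unname(cl$classes[1]), unname(cl$classes[2]))
  expect_equal(sort(unique(unname(cl$classes))), LETTERS[1:4])
  cl1 <- cluster_classes(m, k = 1)
  expect_true(all(cl1$classes == "A"))
  expect_error(cluster_classes(m, k = 13), "exceeds")
})

test_that("class labels are stable under row permutation", {
  m <- rand_set_means(20, 44)
  cl <- cluster_classes(m, k = 3)
  perm <- withr::with_seed(45, sample(nrow(m)))
  cl2 <- cluster_classes(m[perm, ], k = 3)
  expect_equal(cl2$classes[names(cl$classes)], cl$classes)
})

test_that("well-separated planted profiles are recovered and labeled A-E in order", {
  # profile shapes follow the five described classes (wild-type columns)
  shapes <- rbind(A = c(1.5, 15, 70), B = c(25, 700, 5500),
                  C = c(1300, 7800, 24000), D = c(46, 55, 72),
                  E = c(1030, 1270, 1800))
  set.seed(46)
  rows <- do.call(rbind, lapply(rownames(shapes), function(cl) {
    t(replicate(10, shapes[cl, ] * exp(rnorm(1, 0, 0.1))))
  }))
  m <- cbind(rows, rows * 0.5)  # mutant columns, irrelevant to clustering
  dimnames(m) <- list(sprintf("m%02d", 1:50),
                      c("wt.UF0_2h", "wt.F0_2h", "wt.F2_4h",
                        "mut.UF0_2h", "mut.F0_2h", "mut.F2_4h"))
  truth <- rep(rownames(shapes), each = 10)
  cl <- cluster_classes(m, k = 5)
  expect_gte(adjusted_rand_index(cl$classes, truth), 0.999)
  # the relabeling rule puts the nonmaternal class first: label A has the
  # lowest wild-type egg mean
  means_by_label <- tapply(m[, "wt.UF0_2h"], cl$classes, mean)
  expect_equal(names(which.min(means_by_label)), "A")
})

test_that("class_summary reports per-class means and tolerates empty classes", {
  m <- rand_set_means(6, 47)
  classes <- stats::setNames(c("A", "A", "B", "B", "B", "C"), rownames(m))
  cs <- class_summary(classes, m)
  expect_equal(cs$n, c(2L, 3L, 1L))
  expect_equal(cs[cs$class == "A", "wt.F0_2h"], mean(m[1:2, "wt.F0_2h"]))
  expect_equal(cs[cs$class == "C", "mut.F2_4h"],
               unname(m[6, "mut.F2_4h"]))
  cs2 <- class_summary(classes[1:5], m, levels = c("A", "B", "C"))
  expect_equal(cs2$n[cs2$class == "C"], 0L)
  expect_true(is.na(cs2[cs2$class == "C", "wt.UF0_2h"]))
})

test_that("downregulated-miRNA selection combines FDR, direction and RPM", {
  m <- rand_set_means(4, 48)
  m[, ] <- 50  # all expressed
  m[4, ] <- 1  # below the RPM threshold
  de1 <- data.frame(feature = rownames(m), logFC = c(-2, -2, 2, -2),
                    LRT = 1, PValue = 0.01,
                    FDR = c(0.04, 0.2, 0.04, 0.01))
  de2 <- data.frame(feature = rownames(m), logFC = c(1, -1, 1, 1),
                    LRT = 1, PValue = 0.5, FDR = c(0.9, 0.03, 0.9, 0.9))
  got <- select_downregulated_mirnas(list(de1, de2), m)
  # 1: hit in contrast 1; 2: hit in contrast 2; 3: upregulated; 4: low RPM
  expect_equal(got, sort(rownames(m)[1:2]))
})

test_that("isoform subset filters equal a brute-force per-row evaluation", {
  set.seed(49)
  for (rep in 1:5) {
    n <- 30
    mk <- function() {
      m <- matrix(rexp(n * 6, 1 / 8), n, 6)
      dimnames(m) <- list(sprintf("m%02d", 1:n),
                          c("wt.UF0_2h", "wt.F0_2h", "wt.F2_4h",
                            "mut.UF0_2h", "mut.F0_2h", "mut.F2_4h"))
      m
    }
    iso <- list(canonical = mk(), noncanonical = mk(), nta = mk())
    tot <- iso$canonical + iso$noncanonical + iso$nta

    got_nc <- select_noncanonical_subset(iso)
    got_nta <- select_nta_subset(iso)
    for (i in 1:n) {
      sh <- iso$noncanonical[i, ] / tot[i, ]
      c1 <- max(tot[i, ]) >= 10
      c2 <- max(sh) >= 0.5
      c3 <- abs(sh[1] - mean(sh[2:3])) >= 0.2
      expect_equal(got_nc$selected[i], unname(c1 && c2 && c3))
      sh2 <- iso$nta[i, ] / tot[i, ]
      d2 <- sum(sh2 >= 0.2) >= 2
      d3 <- abs(sh2[1] - mean(sh2[2:3])) >= 0.1 ||
        abs(mean(sh2[2:3]) - mean(sh2[5:6])) >= 0.2
      expect_equal(got_nta$selected[i], unname(c1 && d2 && d3))
    }
  }
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_lt(abs(adjusted_rand_index(
    rep(1:2, 50), withr::with_seed(50, sample(rep(1:2, 50))))), 0.15)
})
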