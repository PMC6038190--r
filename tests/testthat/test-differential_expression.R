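# Shared small simulation used by several blocks.
small_sim <- function(seed = 101, n_features = 400L, de_frac = 0.1,
                      lfc = 1.5, dispersion = 0.1) {
  params <- sim_params(n_features = n_features, de_frac = de_frac,
                       lfc = lfc, dispersion = dispersion, seed = seed)
  sr <- simulate_reference(params)
  c(simulate_counts(sr$reference, params, sr$truth), list(params = params))
}

test_that("size_factors reproduces the median-of-ratios worked example", {
  m <- matrix(c(10, 30, 20, 60), ncol = 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  sf <- size_factors(m)
  # geometric means per feature: sqrt(200), sqrt(1800); both ratios equal
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)
  # identical columns give unit factors
  m2 <- matrix(c(5, 9, 5, 9, 5, 9), ncol = 3)
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
})

test_that("size factors are exactly scale-equivariant and match DESeq2", {
  withr::local_seed(5)
  m <- matrix(rnbinom(600, mu = 50, size = 10), ncol = 6,
              dimnames = list(sprintf("f%d", 1:100), sprintf("s%d", 1:6)))
  sf <- size_factors(m)
  m3 <- m
  m3[, 2] <- m3[, 2] * 3L
  # relative normalisation is exactly equivariant: the scaled sample's
  # factor grows threefold relative to every other sample
  sf3 <- size_factors(m3)
  expect_equal(sf3[2] / sf3[1], 3 * sf[2] / sf[1], tolerance = 1e-12)
  skip_if_not_installed("DESeq2")
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-6)
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.001, 0.5, 1.0)), c(0.003, 0.75, 1.0))
  expect_equal(bh_adjust(0.5), 0.5)
  # NA entries are excluded and preserved
  expect_equal(bh_adjust(c(0.001, NA, 0.5, 1.0)), c(0.003, NA, 0.75, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # pointwise >= input and monotone in the ranks of p
  withr::local_seed(8)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= 0))
})

test_that("call_deregulated applies inclusive lfc and strict padj thresholds", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    base_mean = 10, log2fc = c(0.59, -0.7, 1.2, 0.6),
    se = 0.1, stat = 1, p = 0.01,
    padj = c(0.01, 0.09, 0.10, 0.05), status = "tested",
    stringsAsFactors = FALSE
  )
  class(res) <- c("pirsig_de", "data.frame")
  call <- call_deregulated(res)
  expect_false("a" %in% c(call$up, call$down))  # lfc 0.59 < 0.6
  expect_true("b" %in% call$down)               # -0.7 at padj 0.09
  expect_false("c" %in% call$up)                # padj 0.10 not < 0.1
  expect_true("d" %in% call$up)                 # lfc exactly 0.6 counts
  expect_length(intersect(call$up, call$down), 0)
})

test_that("dispersion estimates are near zero for Poisson and near truth for NB", {
  withr::local_seed(17)
  n <- 800L
  g <- factor(rep(c("A", "B"), each = 8))
  pois <- matrix(rpois(n * 16, 100), nrow = n)
  sf <- rep(1, 16)
  expect_lte(median(estimate_dispersions(pois, sf, g)), 0.01)
  nb <- matrix(rnbinom(n * 16, mu = 100, size = 5), nrow = n)
  a <- median(estimate_dispersions(nb, sf, g))
  expect_gte(a, 0.1)
  expect_lte(a, 0.4)
  # degenerate single feature: raw moments, no trend fit
  one <- matrix(rnbinom(16, mu = 100, size = 10), nrow = 1)
  expect_length(estimate_dispersions(one, sf, g), 1L)
})

test_that("nb_wald recovers planted effects and flags all-zero features", {
  sim <- small_sim(seed = 101)
  sim$counts[1, ] <- 0L
  de <- nb_wald(sim$counts, sim$sample_sheet, design_spec("group"))
  expect_s3_class(de, "pirsig_de")
  expect_equal(de$status[1], "untested")
  expect_true(is.na(de$padj[1]))
  tested <- de[de$status == "tested", ]
  expect_true(all(is.finite(tested$stat)))
  expect_true(all(tested$padj >= tested$p - 1e-12))
  truth <- sim$truth
  planted <- truth$feature_id[truth$direction != "null" &
                                truth$feature_id != truth$feature_id[1]]
  sgn <- ifelse(truth$direction == "up", 1, -1)[match(planted, truth$feature_id)]
  est <- de$log2fc[match(planted, de$feature_id)] * sgn
  expect_lt(abs(mean(est, na.rm = TRUE) - 1.5), 0.15)
})

test_that("swapping group labels flips log2fc sign and keeps p-values", {
  sim <- small_sim(seed = 77, n_features = 150L)
  de1 <- nb_wald(sim$counts, sim$sample_sheet, design_spec("group"))
  sheet2 <- sim$sample_sheet
  sheet2$group <- factor(sheet2$group, levels = rev(unique(sheet2$group)))
  de2 <- nb_wald(sim$counts, sheet2, design_spec("group"))
  ok <- de1$status == "tested" & de2$status == "tested"
  expect_equal(de1$log2fc[ok], -de2$log2fc[ok], tolerance = 1e-6)
  expect_equal(de1$p[ok], de2$p[ok], tolerance = 1e-6)
})

test_that("nb_wald log2fc agrees with DESeq2 on the same data", {
  skip_if_not_installed("DESeq2")
  sim <- small_sim(seed = 11, n_features = 300L)
  de <- nb_wald(sim$counts, sim$sample_sheet, design_spec("group"))
  dds <- suppressMessages(DESeq2::DESeqDataSetFromMatrix(
    sim$counts, S4Vectors::DataFrame(group = factor(sim$sample_sheet$group,
                                                    levels = c("CTRL", "PD"))),
    ~group))
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  r <- DESeq2::results(dds, independentFiltering = FALSE, cooksCutoff = FALSE)
  ok <- de$status == "tested" & !is.na(r$log2FoldChange)
  expect_gt(cor(de$log2fc[ok], r$log2FoldChange[ok]), 0.98)
  # deregulation calls agree closely at the shared thresholds
  call_mine <- call_deregulated(de)
  mine <- union(call_mine$up, call_mine$down)
  theirs <- rownames(r)[!is.na(r$padj) & r$padj < 0.1 &
                          abs(r$log2FoldChange) >= 0.6]
  jac <- length(intersect(mine, theirs)) / length(union(mine, theirs))
  expect_gt(jac, 0.7)
})

test_that("nb_wald validates its design", {
  sim <- small_sim(seed = 13, n_features = 50L)
  sheet <- sim$sample_sheet
  sheet$group <- "CTRL"
  expect_error(nb_wald(sim$counts, sheet, design_spec("group")),
               "2 observed levels")
  sheet2 <- sim$sample_sheet
  sheet2$dup <- sheet2$group
  expect_error(nb_wald(sim$counts, sheet2,
                       design_spec("group", "dup")), "rank deficient")
  expect_error(nb_wald(sim$counts, sim$sample_sheet,
                       design_spec("group", "nope")), "lacks column")
})

test_that("log_transform and top_variable behave on constructed matrices", {
  m <- matrix(c(0, 15, 3, 31), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  lt <- log_transform(m, c(1, 1))
  expect_equal(lt["a", "s1"], 0)
  expect_equal(lt["b", "s1"], 4)
  expect_equal(lt["b", "s2"], 5)
  # doubling a size factor halves normalised counts before the log
  lt2 <- log_transform(m, c(1, 2))
  expect_equal(lt2["b", "s2"], log2(31 / 2 + 1))
  mm <- rbind(const1 = c(5, 5, 5), var1 = c(1, 9, 5), const2 = c(2, 2, 2))
  expect_equal(top_variable(mm, 1), "var1")
  expect_equal(top_variable(mm, 10), c("var1", "const1", "const2"))
  # equal-variance tie broken lexicographically
  expect_equal(top_variable(mm, 3)[2:3], c("const1", "const2"))
})

test_that("top_de and top_abundant_de rank and report count share", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    base_mean = c(10, 5, 1, 50),
    log2fc = c(1, -1, 1, 0.1), se = 0.1, stat = 1,
    p = c(0.001, 0.002, 0.001, 0.9),
    padj = c(0.01, 0.01, 0.05, 0.95),
    status = c("tested", "tested", "tested", "untested"),
    stringsAsFactors = FALSE
  )
  class(res) <- c("pirsig_de", "data.frame")
  # padj ties broken by raw p then id; untested excluded
  expect_equal(top_de(res, 2), c("a", "b"))
  expect_equal(top_de(res, 10), c("a", "b", "c"))
  call <- structure(list(up = c("a", "c"), down = "b"),
                    class = "pirsig_call")
  expect_equal(top_abundant_de(res, call, 2)$feature_ids, c("a", "b"))
  # count share on a constructed matrix: called top-2 hold 20% of sample 1
  counts <- matrix(c(10, 10, 1, 79, 5, 5, 1, 9), ncol = 2,
                   dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  sh <- top_abundant_de(res, call, 2, counts = counts, sf = c(1, 1))
  expect_equal(unname(sh$count_share["s1"]), 0.20)
  empty <- structure(list(up = character(0), down = character(0)),
                     class = "pirsig_call")
  sh0 <- top_abundant_de(res, empty, 2, counts = counts, sf = c(1, 1))
  expect_length(sh0$feature_ids, 0)
  expect_equal(unname(sh0$count_share), c(0, 0))
})
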