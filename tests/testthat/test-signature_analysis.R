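# Reference with a controlled class composition for enrichment tests.
class_reference <- function(n_by_class) {
  classes <- rep(names(n_by_class), n_by_class)
  tiny_reference(replicate(length(classes), random_seq(24)), classes,
                 ids = sprintf("q%03d", seq_along(classes)))
}

test_that("origin_enrichment reproduces the closed-form worked instance", {
  withr::local_seed(2)
  # query of 100 with 30 SINE against a null proportion of 0.15
  ref <- class_reference(c(SINE = 30, OTHER = 70))
  np <- c(SINE = 0.15, LINE = 0.1, LTR = 0.1, GENIC = 0.3, OTHER = 0.35,
          UNKNOWN = 0)
  rows <- origin_enrichment(ref$id, ref, np)
  sine <- rows[rows$origin_class == "SINE", ]
  expect_equal(sine$k, 30L)
  expect_equal(sine$expected, 15)
  expect_equal(sine$chi2, 17.6471, tolerance = 1e-4)
  expect_equal(sine$p, 2.67e-5, tolerance = 0.01)
  expect_equal(sine$direction, "enriched")
  # observed exactly at the null: chi2 0, p 1, no direction
  ref2 <- class_reference(c(SINE = 15, OTHER = 85))
  r2 <- origin_enrichment(ref2$id, ref2, np)
  expect_equal(r2$chi2[r2$origin_class == "SINE"], 0)
  expect_equal(r2$p[r2$origin_class == "SINE"], 1)
  expect_equal(r2$direction[r2$origin_class == "SINE"], "none")
  # degenerate null proportion is untestable
  expect_true(r2$untestable[r2$origin_class == "UNKNOWN"])
  expect_error(origin_enrichment(character(0), ref, np), "empty query")
})

test_that("origin_enrichment chi2 equals the independent closed-form oracle", {
  withr::local_seed(4)
  for (i in 1:50) {
    n <- sample(20:300, 1)
    k <- sample(0:n, 1)
    p0 <- round(stats::runif(1, 0.05, 0.95), 3)
    ref <- class_reference(c(SINE = max(k, 1), OTHER = max(n - k, 1)))
    ids <- c(ref$id[as.character(ref$origin_class) == "SINE"][seq_len(k)],
             ref$id[as.character(ref$origin_class) == "OTHER"][seq_len(n - k)])
    np <- c(SINE = p0, OTHER = 1 - p0, LINE = 0, LTR = 0, GENIC = 0,
            UNKNOWN = 0)
    got <- origin_enrichment(ids, ref, np)
    expect_equal(got$chi2[got$origin_class == "SINE"],
                 oracle_gof_chi2(k, n, p0), tolerance = 1e-9)
    # third route: stats::chisq.test without continuity correction
    expect_equal(got$chi2[got$origin_class == "SINE"],
                 unname(suppressWarnings(
                   stats::chisq.test(c(k, n - k), p = c(p0, 1 - p0),
                                     correct = FALSE)$statistic)),
                 tolerance = 1e-9)
  }
})

test_that("class counts partition the query set", {
  withr::local_seed(6)
  ref <- class_reference(c(SINE = 20, LINE = 15, LTR = 5, GENIC = 30,
                           OTHER = 20, UNKNOWN = 10))
  q <- sample(ref$id, 40)
  np <- origin_proportions(ref)
  rows <- origin_enrichment(q, ref, np)
  expect_equal(sum(rows$k), 40L)
})

test_that("composition_bias contrasts deregulated sets against the universe", {
  withr::local_seed(9)
  ref <- tiny_reference(replicate(30, random_seq(26)))
  # up = universe: differences vanish
  cb <- composition_bias(ref$id, character(0), ref$id, ref)
  expect_true(all(cb$diff_up[cb$denom_all > 0] == 0))
  # single-sequence sets: profiles are 0/1 indicators
  cb1 <- composition_bias(ref$id[1], ref$id[2], ref$id, ref)
  expect_true(all(cb1$frac_up[cb1$denom_up > 0] %in% c(0, 1)))
  expect_error(composition_bias(ref$id[1], ref$id[1], ref$id, ref),
               "disjoint")
  expect_error(composition_bias(ref$id[1], ref$id[2], character(0), ref),
               "empty universe")
})

test_that("planted cytosine bias shows up as an up-vs-all difference", {
  params <- sim_params(n_features = 2000L, de_frac = 0.1, frac_de_down = 0.5,
                       c_bias_prob = 0.6, seed = 23)
  sr <- simulate_reference(params)
  up <- sr$truth$feature_id[sr$truth$direction == "up"]
  down <- sr$truth$feature_id[sr$truth$direction == "down"]
  cb <- composition_bias(up, down, sr$reference$id, sr$reference)
  expect_true(all(cb$diff_up[2:9] > 0.2))
  expect_true(all(abs(cb$diff_down[2:9]) < 0.15))
  expect_true(all(2:9 %in% attr(cb, "flagged_up")))
})

test_that("memory_fraction counts stage calls already deregulated earlier", {
  call_of <- function(up, down) {
    structure(list(up = up, down = down), class = "pirsig_call")
  }
  fibro <- call_of(c("a", "b"), "c")
  neuron <- call_of(c("b", "d"), c("c", "e"))
  mf <- memory_fraction(neuron, fibro)
  expect_equal(mf$n_memory, 2L)          # b and c
  expect_equal(mf$n_total_deregulated, 4L)
  expect_equal(mf$fraction, 0.5)
  # direction flag: membership-only counts an up/down flip, matched does not
  f2 <- call_of("a", character(0))
  n2 <- call_of(character(0), "a")
  expect_equal(memory_fraction(n2, f2)$fraction, 1)
  expect_equal(memory_fraction(n2, f2, direction_matched = TRUE)$fraction, 0)
  # disjoint calls
  expect_equal(memory_fraction(call_of("x", "y"), fibro)$fraction, 0)
  expect_error(memory_fraction(call_of(character(0), character(0)), fibro),
               "empty stage call")
  # matched is never above membership-only
  withr::local_seed(15)
  ids <- sprintf("f%02d", 1:40)
  for (i in 1:10) {
    a <- call_of(sample(ids, 8), sample(setdiff(ids, 1:8), 8))
    b <- call_of(sample(ids, 10), sample(ids, 5))
    b$down <- setdiff(b$down, b$up)
    expect_lte(memory_fraction(a, b, TRUE)$fraction,
               memory_fraction(a, b, FALSE)$fraction)
  }
})

test_that("direction_overlap is stratified by direction and symmetric", {
  call_of <- function(up, down) {
    structure(list(up = up, down = down), class = "pirsig_call")
  }
  a <- call_of(c("x", "y"), c("d1", "d2"))
  b <- call_of(c("y", "z"), c("d2", "d3"))
  ov <- direction_overlap(a, b)
  expect_equal(ov$n_up_shared, 1L)
  expect_equal(ov$n_down_shared, 1L)
  expect_equal(ov$n_shared, 2L)
  ba <- direction_overlap(b, a)
  expect_equal(ov$n_shared, ba$n_shared)
  expect_setequal(ov$up_shared, ba$up_shared)
  # opposite directions never count
  ov2 <- direction_overlap(call_of("x", character(0)),
                           call_of(character(0), "x"))
  expect_equal(ov2$n_shared, 0L)
  ov3 <- direction_overlap(call_of(character(0), character(0)),
                           call_of(character(0), character(0)))
  expect_equal(ov3$n_shared, 0L)
})

test_that("hcluster separates duplicated sample blocks perfectly", {
  withr::local_seed(19)
  base <- matrix(rnorm(50 * 2, sd = 2), 50, 2)
  m <- cbind(base[, 1] + matrix(rnorm(50 * 4, sd = 0.05), 50, 4),
             base[, 2] + matrix(rnorm(50 * 4, sd = 0.05), 50, 4))
  dimnames(m) <- list(sprintf("f%d", 1:50), sprintf("s%d", 1:8))
  sheet <- data.frame(sample_id = colnames(m),
                      group = rep(c("CTRL", "PD"), each = 4))
  cl <- hcluster(m, rownames(m), sheet)
  expect_equal(cl$ari, 1.0)
  # permuted labels give near-zero ARI on average
  aris <- replicate(100, {
    sheet2 <- sheet
    sheet2$group <- sample(sheet2$group)
    hcluster(m, rownames(m), sheet2)$ari
  })
  expect_lt(abs(mean(aris)), 0.2)
  # constant sample column is an error naming the sample
  m2 <- m
  m2[, 3] <- 5
  expect_error(hcluster(m2, rownames(m2), sheet), "s3")
})
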