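toy_cpm <- function() {
  m <- matrix(c(10, 20, 30, 40,
                20, 40, 60, 80,
                5, 5, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  attr(m, "layer") <- "intron"
  m
}

test_that("mean TFA averages eligible targets only", {
  m <- toy_cpm()
  hi <- c(g1 = TRUE, g2 = FALSE, g3 = TRUE)
  # single-target regulon equals that gene's CPM
  expect_equal(unname(tfa_mean(m, "g1", hi)), unname(m["g1", ]),
               ignore_attr = TRUE)
  # intronless g2 excluded on the intron layer
  act <- tfa_mean(m, c("g1", "g2"), hi)
  expect_equal(unname(act), unname(m["g1", ]), ignore_attr = TRUE)
  expect_equal(attr(act, "n_targets"), 1L)
  # exon layer keeps all targets by default...
  attr(m, "layer") <- "exon"
  expect_equal(unname(tfa_mean(m, c("g1", "g2"), hi)),
               unname(colMeans(m[c("g1", "g2"), ])), ignore_attr = TRUE)
  # ...unless a matched gene set is requested
  expect_equal(unname(tfa_mean(m, c("g1", "g2"), hi,
                               matched_gene_set = TRUE)),
               unname(m["g1", ]), ignore_attr = TRUE)
  # idempotence: identical targets give their common value
  attr(m, "layer") <- "intron"
  m2 <- rbind(m, g4 = m["g1", ])
  attr(m2, "layer") <- "intron"
  expect_equal(tfa_mean(m2, c("g1", "g4"), c(hi, g4 = TRUE))[["s1"]],
               m["g1", "s1"])
  # missing target warns; none eligible errors naming the TF
  expect_warning(tfa_mean(m, c("g1", "nope"), hi, tf = "TFX"), "nope")
  expect_error(suppressWarnings(tfa_mean(m, "g2", hi, tf = "TFX")), "TFX")
})

test_that("mean TFA is linear in CPM and order-invariant", {
  m <- toy_cpm()
  hi <- c(g1 = TRUE, g2 = TRUE, g3 = TRUE)
  t1 <- tfa_mean(m, c("g1", "g3"), hi)
  t2 <- tfa_mean(m, c("g3", "g1"), hi)
  expect_equal(t1, t2)
  m5 <- m * 5
  attr(m5, "layer") <- "intron"
  expect_equal(unname(tfa_mean(m5, c("g1", "g3"), hi)), unname(t1) * 5)
})

test_that("rank-AUC scores recovery of the regulon at the top", {
  expr <- setNames(seq(100, 1, length.out = 100), paste0("g", 1:100))
  # regulon occupying exactly the top ranks scores 1
  expect_equal(tfa_rank_auc(expr, paste0("g", 1:5), top_fraction = 0.1), 1)
  # no target in universe scores 0 with a warning
  expect_warning(s0 <- tfa_rank_auc(expr, "absent"), "score 0")
  expect_equal(s0, 0)
  # invariance under strictly monotone transforms of expression
  tg <- paste0("g", c(3, 20, 77))
  s1 <- tfa_rank_auc(expr, tg, 0.2)
  s2 <- tfa_rank_auc(log1p(expr), tg, 0.2)
  s3 <- tfa_rank_auc(expr^3, tg, 0.2)
  expect_equal(s1, s2)
  expect_equal(s1, s3)
  expect_error(tfa_rank_auc(expr, tg, 0), "top_fraction")
})

test_that("rank-AUC under random rankings matches the hypergeometric mean", {
  # closed-form oracle: with m targets in a universe of N, the expected
  # recovery at rank i is i*m/N, so E[score] = (m/N) * sum(i) / max_area
  N <- 50; m <- 5; top <- 0.2
  n_top <- floor(top * N)
  max_area <- sum(pmin(seq_len(n_top), m))
  oracle <- (m / N) * sum(seq_len(n_top)) / max_area
  genes <- paste0("g", seq_len(N))
  tg <- paste0("g", 1:m)
  set.seed(21)
  scores <- replicate(10000, {
    expr <- setNames(sample(N), sample(genes))  # random ranking
    tfa_rank_auc(expr, tg, top)
  })
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores) - oracle), 3 * se)
})

test_that("z-scoring, fold change and the null percentile behave", {
  x <- c(2, 6, 4)
  z <- zscore_series(x)
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)
  expect_equal(zscore_series(3 * x + 7), z)  # affine invariance
  expect_warning(zc <- zscore_series(c(5, 5, 5)), "constant")
  expect_equal(unname(zc), c(0, 0, 0))
  expect_equal(fold_change(c(2, 6, 4)), 3)
  expect_equal(fold_change(c(1, 1, 1)), 1)
  expect_equal(fold_change(10 * c(2, 6, 4)), 3)  # scale invariance
  expect_error(fold_change(c(0, 1)), "positive")

  nulls <- seq_len(1000)
  expect_equal(null_percentile(2000, nulls)$p_value, 1 / 1001)
  expect_equal(null_percentile(500.5, nulls)$percentile, 50)
  expect_error(null_percentile(1, 1:50), "at least 100")
  # sort-based oracle on 200 nulls
  set.seed(31)
  ns <- rnorm(200)
  act <- 0.3
  res <- null_percentile(act, ns)
  expect_equal(res$p_value, (1 + sum(sort(ns, decreasing = TRUE) >= act)) / 201)
  expect_equal(res$percentile, 100 * mean(ns < act))
})

test_that("TF expression filter uses intron plus exon CPM", {
  ic <- matrix(c(0, 0, 0, 1, 0, 0), 3, 2,
               dimnames = list(c("tfA", "tfB", "tfC"), c("s1", "s2")))
  ec <- matrix(c(0, 2, 0, 0, 0, 0), 3, 2, dimnames = dimnames(ic))
  # tfA expressed in s2 (intron), tfB in s1 (exon), tfC never
  expect_setequal(expressed_tf_filter(ic, ec, c("tfA", "tfB", "tfC")),
                  c("tfA", "tfB"))
  expect_warning(out <- expressed_tf_filter(ic, ec, c("tfA", "ghost")),
                 "ghost")
  expect_equal(out, "tfA")
  expect_length(expressed_tf_filter(ic, ec, character()), 0)
})
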