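test_that("cosinor recovers a noiseless harmonic exactly", {
  t <- seq(0, 22, by = 2)
  x <- 3 + 2 * cos(2 * pi * (t - 6) / 24)
  r <- cosinor_test(x, t, period = 24)
  expect_lt(abs(r$phase - 6), 1e-6)
  expect_lt(r$p_value, 1e-10)
  expect_equal(r$amplitude, 2, tolerance = 1e-8)
  expect_equal(r$mesor, 3, tolerance = 1e-8)
})

test_that("cosinor handles degenerate inputs explicitly", {
  t <- seq(0, 22, by = 2)
  expect_warning(r <- cosinor_test(rep(1, 12), t), "constant")
  expect_equal(r$p_value, 1)
  expect_equal(r$amplitude, 0)
  expect_error(cosinor_test(1:4, 1:4), "at least 5")
  expect_error(cosinor_test(1:6, seq(0, 10, by = 2)), "half a period")
})

test_that("cosinor phase is equivariant under time shifts", {
  t <- seq(0, 22, by = 2)
  set.seed(3)
  x <- 5 + 1.5 * cos(2 * pi * (t - 4) / 24) + rnorm(12, 0, 0.1)
  base <- cosinor_test(x, t)$phase
  for (shift in c(2, 7.5, 13)) {
    shifted <- cosinor_test(x, t - shift)$phase
    expect_equal((shifted + shift) %% 24, base %% 24, tolerance = 1e-8)
  }
})

test_that("TF classification combines the two layers' rhythm calls", {
  r <- function(p) list(p_value = p)
  expect_equal(classify_tf(r(0.01), r(0.01)), "class1")
  expect_equal(classify_tf(r(0.01), r(0.2)), "class2")
  expect_equal(classify_tf(r(0.2), r(0.01)), "class3")
  expect_equal(classify_tf(r(0.2), r(0.9)), "none")
})

test_that("phase differences wrap with exon-lags-intron positive", {
  expect_equal(phase_difference(8, 6), 2)
  expect_equal(phase_difference(1, 23), 2)  # wraps across midnight
  expect_equal(phase_difference(6, 6), 0)
  expect_equal(phase_difference(0, 12), 12)  # half-period maps to +12
  # antisymmetric except at exactly half a period
  for (a in seq(0, 23.5, by = 3.5)) for (b in seq(0, 23.5, by = 2.5)) {
    d <- phase_difference(a, b)
    if (abs(d) != 12) expect_equal(phase_difference(b, a), -d)
  }
})

test_that("linear interpolation reproduces nodes and refuses extrapolation", {
  t <- c(0, 1, 2.5, 4, 5, 7.5)
  x <- c(1, 3, 2, 5, 4, 0)
  grid <- seq(0, 7.5, by = 0.5)
  y <- interpolate_linear(x, t, grid)
  expect_length(y, 16)
  expect_equal(interpolate_linear(x, t, t), x)
  expect_equal(interpolate_linear(x[1:2], c(0, 2), 1), mean(x[1:2]))
  expect_error(interpolate_linear(x, t, 8), "extrapolate")
})

test_that("surrogate correlation works across mismatched sampling grids", {
  t1 <- seq(0, 12, by = 1)
  act <- sin(2 * pi * t1 / 12)
  expect_equal(correlate_with_surrogate(act, t1, act, t1)$r, 1)
  expect_equal(correlate_with_surrogate(act, t1, -act, t1)$r, -1)
  # surrogate on a shifted/coarser grid still correlates strongly
  t2 <- seq(0, 7.5, by = 1.5)
  surr <- sin(2 * pi * t2 / 12)
  res <- correlate_with_surrogate(act, t1, surr, t2)
  expect_gt(res$r, 0.9)
  expect_equal(res$n, 16)  # 0 to 7.5 by 0.5
  expect_error(correlate_with_surrogate(act, t1, surr, t2,
                                        grid_times = c(0, 1)), "3 shared")
})

test_that("per-gene performance filters, ratios and associates", {
  times <- 1:8
  surr <- cos(2 * pi * times / 8)
  lagged <- cos(2 * pi * (times - 1.5) / 8)
  ic <- rbind(hiA = 10 + 5 * surr,
              hiB = 10 + 5 * surr,
              low = 0.5 + 0.1 * surr)
  ec <- rbind(hiA = 10 + 5 * surr,        # tracks as well as intron
              hiB = 10 + 5 * lagged,      # tracks worse
              low = 0.5 + 0.1 * surr)
  colnames(ic) <- colnames(ec) <- paste0("s", times)
  res <- per_gene_performance(ic, ec, surr,
                              half_lives = c(hiA = 30, hiB = 600))
  expect_setequal(res$per_gene$gene, c("hiA", "hiB"))  # low filtered out
  expect_equal(res$per_gene$ratio[res$per_gene$gene == "hiA"], 1)
  expect_gt(res$per_gene$ratio[res$per_gene$gene == "hiB"], 1)
  # engineered fixture: exon tracking degrades with half-life
  set.seed(5)
  hls <- seq(30, 900, length.out = 12)
  ic2 <- t(sapply(hls, function(h) 10 + 5 * surr + rnorm(8, 0, 0.05)))
  ec2 <- t(sapply(hls, function(h) {
    lag <- 8 * atan(h / 300) / (2 * pi)
    10 + 5 * cos(2 * pi * (times - lag) / 8) + rnorm(8, 0, 0.05)
  }))
  rownames(ic2) <- rownames(ec2) <- paste0("g", seq_along(hls))
  colnames(ic2) <- colnames(ec2) <- paste0("s", times)
  res2 <- per_gene_performance(ic2, ec2, surr,
                               setNames(hls, rownames(ic2)))
  expect_gt(res2$association$r, 0)
  expect_warning(per_gene_performance(ic * 0 + 0.1, ec * 0 + 0.1, surr),
                 "high-expression")
})

test_that("replicate robustness counts rhythmic leave-one-out subsets", {
  t <- seq(0, 22, by = 2)
  clean <- matrix(rep(5 + 2 * cos(2 * pi * (t - 6) / 24), 4), 4,
                  byrow = TRUE)
  expect_equal(replicate_robustness(clean, t), 1.0)
  set.seed(17)
  noise <- matrix(rnorm(4 * 12), 4)
  expect_lt(replicate_robustness(noise, t), 0.75)
  expect_error(replicate_robustness(clean[1:2, ], t), "3 replicates")
  # all proper subsets of >= 2 replicates: choose(4,2) + choose(4,3) = 10
  expect_equal(replicate_robustness(clean, t, subsets = "all"), 1.0)
})

test_that("module clustering recovers planted anti-correlated groups", {
  t <- seq(0, 22, by = 2)
  set.seed(9)
  up <- cos(2 * pi * (t - 6) / 24)
  a <- rbind(A1 = up, A2 = 3 * up + 1, B1 = -up, B2 = -2 * up + 5) +
    matrix(rnorm(48, 0, 0.05), 4)
  cl <- cluster_modules(a, k = 2)
  expect_equal(cl$modules[["A1"]], cl$modules[["A2"]])
  expect_equal(cl$modules[["B1"]], cl$modules[["B2"]])
  expect_false(cl$modules[["A1"]] == cl$modules[["B1"]])
  expect_equal(sort(unique(cl$modules)), 1:2)
  # invariance to row order and per-TF affine rescaling
  perm <- a[c(3, 1, 4, 2), ]
  cl2 <- cluster_modules(perm, k = 2)
  agree <- outer(cl$modules[rownames(perm)], cl$modules[rownames(perm)], "==")
  agree2 <- outer(cl2$modules, cl2$modules, "==")
  expect_equal(unname(agree), unname(agree2))
  resc <- a * 2 + 3
  expect_equal(cluster_modules(resc, k = 2)$modules, cl$modules)
  # duplicate series land together; constants are excluded with a warning
  dup <- rbind(a, A1copy = a["A1", ])
  cl3 <- cluster_modules(dup, k = 2)
  expect_equal(cl3$modules[["A1copy"]], cl3$modules[["A1"]])
  expect_warning(cluster_modules(rbind(a, flat = rep(1, 12)), k = 2),
                 "constant")
})

test_that("phase-difference vs intron-length association is a plain Pearson", {
  pd <- setNames(c(1, 2, 3, 4, 5), paste0("tf", 1:5))
  expect_equal(target_intron_length_association(pd, pd)$r, 1)
  # orthogonalised fixture: lengths constructed uncorrelated with pd
  len <- setNames(c(2, 1, 5, 3, 4), paste0("tf", 1:5))
  len_orth <- setNames(residuals(lm(len ~ pd)), names(len))
  res <- target_intron_length_association(pd, len_orth)
  expect_lt(abs(res$r), 1e-8)
  expect_error(target_intron_length_association(pd[1:3], pd[1:3]), "4 TFs")
})
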