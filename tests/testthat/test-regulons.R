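toy_regulons <- function() {
  regulon_set(data.frame(
    tf = c("p53", "p53", "p53", "p53", "nfkb"),
    target = c("a", "b", "c", "d", "a"),
    mode = c("activation", "activation", "activation", "repression",
             "activation"),
    confidence = c("A", "B", "C", "A", "B")))
}

test_that("regulon tables validate and round-trip", {
  reg <- toy_regulons()
  path <- tempfile(fileext = ".tsv")
  write.table(as.data.frame(reg), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_equal(as.data.frame(load_regulons(path)), as.data.frame(reg))
  expect_error(regulon_set(data.frame(tf = "x", target = "y",
                                      mode = "activation",
                                      confidence = "F")), "grade")
  expect_error(regulon_set(data.frame(tf = "x", target = "y",
                                      mode = "binds", confidence = "A")),
               "mode")
  expect_error(regulon_set(data.frame(tf = c("x", "x"),
                                      target = c("y", "y"),
                                      mode = "activation",
                                      confidence = c("A", "B"))),
               "duplicate")
})

test_that("confidence and mode filtering follow the A<B<C<D<E order", {
  reg <- toy_regulons()
  expect_setequal(filter_regulon(reg, "p53", "B"), c("a", "b"))
  expect_setequal(filter_regulon(reg, "p53", "C"), c("a", "b", "c"))
  # repression edge admitted only when activation_only is off
  expect_true("d" %in% filter_regulon(reg, "p53", "B",
                                      activation_only = FALSE))
  expect_error(filter_regulon(reg, "jun"), "available.*nfkb")
  # monotone in max_grade
  for (g1 in c("A", "B", "C", "D")) {
    g2 <- LETTERS[match(g1, LETTERS) + 1]
    expect_true(all(filter_regulon(reg, "p53", g1) %in%
                      filter_regulon(reg, "p53", g2)))
  }
})

test_that("half-life split is a deterministic median split", {
  hl <- c(a = 10, b = 20, c = 300, d = 400)
  sp <- split_by_halflife(c("a", "b", "c", "d"), hl)
  expect_equal(sp$short, c("a", "b"))
  expect_equal(sp$long, c("c", "d"))
  # unannotated target excluded from both halves
  sp2 <- split_by_halflife(c("a", "b", "c", "d", "zz"), hl)
  expect_false("zz" %in% c(sp2$short, sp2$long))
  # all-equal half-lives: deterministic equal-size split by gene id
  hl_eq <- setNames(rep(100, 4), c("d", "c", "b", "a"))
  sp3 <- split_by_halflife(c("d", "c", "b", "a"), hl_eq)
  expect_equal(sp3$short, c("a", "b"))
  expect_equal(sp3$long, c("c", "d"))
  expect_error(split_by_halflife(c("a", "zz"), hl), "at least 2")
})

test_that("random regulons exclude true targets and are calibrated", {
  universe <- paste0("g", 1:60)
  exclude <- paste0("g", 1:10)
  regs <- random_regulons(universe, exclude, size = 10, n = 1000, seed = 8)
  expect_length(regs, 1000)
  expect_true(all(lengths(regs) == 10))
  expect_false(any(unlist(regs) %in% exclude))
  # per-gene inclusion frequency ~ size/|eligible| = 10/50
  freq <- table(factor(unlist(regs), levels = setdiff(universe, exclude)))
  p <- 10 / 50
  se <- sqrt(p * (1 - p) / 1000)
  expect_true(all(abs(freq / 1000 - p) < 4 * se))
  expect_error(random_regulons(universe, universe, size = 5), "smaller")
})

test_that("peak refinement keeps TSS within the window and no more", {
  tss <- data.frame(gene = c("a", "b", "c"), chrom = "chr1",
                    strand = c("+", "-", "+"),
                    tss = c(5000L, 10000L, 50000L))
  peaks <- data.frame(chrom = "chr1", start = 4900L, end = 5100L)
  # a: inside the peak; b: 4900 bp away > 2 kb window; c: far away
  expect_equal(refine_by_peaks(c("a", "b", "c"), tss, peaks), "a")
  # window boundary: TSS exactly at end + window - 1 kept, at end + window dropped
  tss2 <- data.frame(gene = c("edge", "out"), chrom = "chr1", strand = "+",
                     tss = c(5100L + 2000L - 1L, 5100L + 2000L))
  expect_equal(refine_by_peaks(c("edge", "out"), tss2, peaks), "edge")
  # widening the window never shrinks the refined set
  w1 <- refine_by_peaks(c("a", "b", "c"), tss, peaks, window = 2000)
  w2 <- refine_by_peaks(c("a", "b", "c"), tss, peaks, window = 6000)
  expect_true(all(w1 %in% w2))
  # empty peak set and missing TSS
  expect_equal(refine_by_peaks("a", tss, peaks[0, ]), character())
  expect_warning(out <- refine_by_peaks(c("a", "nope"), tss, peaks),
                 "nope")
  expect_equal(out, "a")
})

test_that("half-life and TSS loaders validate their columns", {
  p <- tempfile()
  writeLines(c("gene\thalf_life_min", "a\t100", "b\t-5"), p)
  expect_error(load_halflife_table(p), "positive")
  writeLines(c("gene\thalf_life_min", "a\t100", "b\t50"), p)
  expect_equal(load_halflife_table(p), c(a = 100, b = 50))
  writeLines(c("gene\tchrom\tstrand\ttss", "a\tchr1\t+\t100"), p)
  expect_equal(load_tss_table(p)$tss, 100)
  writeLines(c("chr1\t10\t5"), p)
  expect_error(load_peaks_bed(p), "start < end")
})

test_that("TSS extraction from GTF takes the 5'-most start, 0-based", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "transcript", "101", "500", ".", "+", ".",
          'gene_id "gA";', sep = "\t"),
    paste("chr1", "src", "transcript", "151", "600", ".", "+", ".",
          'gene_id "gA";', sep = "\t"),
    paste("chr2", "src", "transcript", "1001", "2000", ".", "-", ".",
          'gene_id "gB";', sep = "\t")), gtf)
  tss <- load_tss_table(gtf)
  expect_equal(tss$tss[tss$gene == "gA"], 100)   # min start, 0-based
  expect_equal(tss$tss[tss$gene == "gB"], 1999)  # minus strand: max end
})
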