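rl <- load_rubric("loss")
rg <- load_rubric("gain")
ann <- tiny_annotation()

test_that("section 1 returns exactly one of 1A/1B, by genomic content", {
  # overlaps a protein-coding gene -> 1A
  a <- assign_section1(one_cnv("1", 1e6, 1.2e6), ann, rl)
  expect_equal(a$category_code, "1A")
  expect_equal(a$points, 0)
  expect_equal(a$provenance, "auto")
  # void of content -> 1B at its (negative) default
  b <- assign_section1(one_cnv("4", 1e7, 1.1e7, "loss"), ann, rl)
  expect_equal(b$category_code, "1B")
  expect_equal(b$points, -0.6)
  # a biotype="other" feature is not content
  j <- assign_section1(one_cnv("2", 2.9e6, 3.2e6), ann, rl)
  expect_equal(j$category_code, "1B")
  # but other_functional_element is
  f <- assign_section1(one_cnv("2", 0.9e6, 1.1e6), ann, rl)
  expect_equal(f$category_code, "1A")
  # totality over random CNVs
  set.seed(21)
  for (i in 1:40) {
    s <- sample(1e7, 1)
    x <- assign_section1(one_cnv(sample(c("1", "2", "3", "4"), 1),
                                 s, s + sample(2e6, 1)), ann, rl)
    expect_equal(nrow(x), 1)
    expect_true(x$category_code %in% c("1A", "1B"))
  }
})

test_that("section 2 loss: containment gives 2A, benign containment 2F,
           partial overlap only flags", {
  # loss fully containing the established HI gene
  s2 <- assign_section2(one_cnv("1", 0.9e6, 1.2e6), ann, rl)
  expect_true("2A" %in% s2$assignments$category_code)
  expect_equal(s2$assignments$points[s2$assignments$category_code == "2A"], 1)
  # loss inside the established benign region
  s2b <- assign_section2(one_cnv("3", 2e6, 3e6), ann, rl)
  expect_equal(s2b$assignments$category_code, "2F")
  expect_equal(s2b$assignments$points, -1)
  # partial overlap of the HI gene: no points, a review flag
  s2c <- assign_section2(one_cnv("1", 1.05e6, 1.2e6), ann, rl)
  expect_equal(nrow(s2c$assignments), 0)
  expect_match(s2c$flags, "partial overlap", all = FALSE)
})

test_that("section 2 never applies uncurated records as established", {
  # the uncurated reported syndrome region on chr1 (4-9 Mb)
  s2 <- assign_section2(one_cnv("1", 4e6, 9e6), ann, rl)
  expect_false("2A" %in% s2$assignments$category_code)
  expect_match(s2$flags, "uncurated", all = FALSE)
  # randomized audit: flip curation flags and check no points ever come
  # from a curated=FALSE record
  set.seed(31)
  for (i in 1:20) {
    regs <- ann$regions
    regs$curated <- sample(c(TRUE, FALSE), nrow(regs), replace = TRUE)
    ann_i <- annotation_set(ann$genes, regs)
    s <- sample(9e6, 1)
    cnv_i <- one_cnv(sample(c("1", "2", "3", "4"), 1), s, s + sample(5e6, 1))
    out <- assign_section2(cnv_i, ann_i, rl)
    if (nrow(out$assignments) > 0) {
      # every emitted code must be justified by some curated record
      expect_true(all(out$assignments$category_code %in% c("2A", "2F")))
      hit <- regions_in(cnv_i, ann_i)
      expect_true(any(hit$curated))
    }
  }
})

test_that("section 2 gain: breakpoint in HI gene -> 2K, spanned HI gene -> 2J,
           never both", {
  # breakpoint inside HIA (1e6-1.1e6)
  k <- assign_section2(one_cnv("1", 1.05e6, 3e6, "gain", "g1"), ann, rg)
  expect_equal(k$assignments$category_code, "2K")
  expect_equal(k$assignments$points, 0.45)
  # gain fully containing HIA, breakpoints outside
  j <- assign_section2(one_cnv("1", 0.5e6, 3e6, "gain", "g2"), ann, rg)
  expect_equal(j$assignments$category_code, "2J")
  expect_equal(j$assignments$points, 0)
  # boundary counts as inside (breakpoint resolution is unreliable)
  kb <- assign_section2(one_cnv("1", 1e6, 3e6, "gain", "g3"), ann, rg)
  expect_equal(kb$assignments$category_code, "2K")
  # TS gene containment for a gain -> 2A
  ts <- assign_section2(one_cnv("2", 0.5e6, 2e6, "gain", "g4"), ann, rg)
  expect_true("2A" %in% ts$assignments$category_code)
  # 2J/2K exclusivity over random gains
  set.seed(17)
  for (i in 1:40) {
    s <- sample(9e6, 1)
    g <- one_cnv("1", s, s + sample(4e6, 1), "gain", sprintf("r%d", i))
    codes <- assign_section2(g, ann, rg)$assignments$category_code
    expect_lte(sum(codes %in% c("2J", "2K")), 1)
  }
})

test_that("section 3 maps gene counts through the rubric bins", {
  # 10 genes -> 3A (0); 30 -> 3B (0.45); 40 -> 3C (0.90) for a loss
  for (case in list(list(10, "3A", 0), list(30, "3B", 0.45),
                    list(40, "3C", 0.9))) {
    n <- case[[1]]
    grid <- gene_grid(n)
    cnv <- one_cnv("1", 1, 1e6 + n * 1e5)
    a <- assign_section3(cnv, grid, rl)
    expect_equal(a$category_code, case[[2]])
    expect_equal(a$points, case[[3]])
    expect_match(a$justification, as.character(n))
  }
  # gain bins differ: 40 genes is still 3B for a gain
  grid40 <- gene_grid(40)
  g <- one_cnv("1", 1, 1e6 + 40 * 1e5, "gain", "g1")
  expect_equal(assign_section3(g, grid40, rg)$category_code, "3B")
  # a 40-member family collapsed counts as one gene -> 0 points
  fam <- gene_grid(40, family = "BIGFAM")
  cnv40 <- one_cnv("1", 1, 1e6 + 40 * 1e5)
  expect_equal(assign_section3(cnv40, fam, rl, TRUE)$points, 0)
  expect_equal(assign_section3(cnv40, fam, rl, FALSE)$points, 0.9)
})

test_that("section 3 points are non-decreasing in gene count", {
  pts <- vapply(c(0, 1, 24, 25, 34, 35, 60, 200), function(n) {
    grid <- gene_grid(max(n, 1))
    cnv <- one_cnv("1", 1, 1e6 + max(n, 1) * 1e5)
    if (n == 0) cnv <- one_cnv("2", 1, 100)  # off-grid: zero genes
    assign_section3(cnv, grid, rl)$points
  }, numeric(1))
  expect_true(all(diff(pts) >= 0))
})

test_that("auto evidence is deterministic end to end", {
  cnv <- one_cnv("1", 0.9e6, 5.6e6)
  w1 <- auto_worksheet(cnv, ann, rl)
  w2 <- auto_worksheet(cnv, ann, rl)
  expect_identical(w1, w2)
  # annotation row order must not matter
  shuf <- annotation_set(ann$genes[sample(nrow(ann$genes)), ],
                         ann$regions[sample(nrow(ann$regions)), ])
  expect_identical(auto_worksheet(cnv, shuf, rl), w1)
})
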