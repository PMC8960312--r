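test_that("shipped rubrics carry the anchored category points", {
  rg <- load_rubric("gain")
  expect_equal(rubric_category(rg, "2K")$default_points, 0.45)
  expect_equal(rubric_category(rg, "2J")$default_points, 0)
  rl <- load_rubric("loss")
  expect_equal(rubric_category(rl, "1B")$default_points, -0.6)
  expect_equal(rubric_category(rl, "2A")$default_points, 1)
  expect_error(rubric_category(rl, "NOPE"), "unknown category")
})

test_that("rubric config round-trips through write_rubric/load_rubric", {
  for (dt in c("loss", "gain")) {
    rb <- load_rubric(dt)
    tmp <- withr::local_tempfile(fileext = ".json")
    write_rubric(rb, tmp)
    rb2 <- load_rubric(dt, config = tmp)
    expect_equal(rb2$categories, rb$categories)
    expect_equal(rb2$thresholds, rb$thresholds)
    expect_equal(lapply(rb2$exclusive, unlist), lapply(rb$exclusive, unlist))
  }
})

test_that("custom rubric configs are honoured and validated", {
  rb <- load_rubric("loss")
  rb$categories <- rbind(rb$categories, data.frame(
    code = "9Z", section = 5, default_points = 0.3, min_points = 0,
    max_points = 0.3, count_min = NA_real_, count_max = NA_real_,
    description = "custom"))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_rubric(rb, tmp)
  expect_equal(
    rubric_category(load_rubric("loss", config = tmp), "9Z")$default_points,
    0.3)
  # duplicate code rejected with the offending code named
  rb_bad <- rb
  rb_bad$categories <- rbind(rb_bad$categories, rb_bad$categories[1, ])
  write_rubric(rb_bad, tmp)
  expect_error(load_rubric("loss", config = tmp), "1A")
  # inverted range rejected
  rb_inv <- load_rubric("loss")
  rb_inv$categories$min_points[3] <- 99
  write_rubric(rb_inv, tmp)
  expect_error(load_rubric("loss", config = tmp), "inverted|range")
  # dosage-type mismatch rejected
  expect_error(load_rubric("gain", config = rb$source), "dosage_type")
})

test_that("validate_assignment enforces membership and ranges", {
  rg <- load_rubric("gain")
  expect_silent(validate_assignment(rg, ev_assign("2K", 0.45)))
  expect_error(validate_assignment(rg, ev_assign("2K", 5)), "out of range")
  expect_error(validate_assignment(rg, ev_assign("NOPE", 0)),
               "unknown category")
  # range endpoints are inclusive
  expect_silent(validate_assignment(rg, ev_assign("4E", 0.3)))
  expect_silent(validate_assignment(rg, ev_assign("4I", -0.45)))
})

test_that("total_score sums, rejects duplicates and exclusive pairs", {
  expect_equal(total_score(ev_assign(character(0), numeric(0))), 0)
  expect_equal(total_score(ev_assign("2K", 0.45)), 0.45)
  expect_equal(total_score(ev_assign(c("1A", "2A", "3A"), c(0, 1, 0))), 1)
  expect_error(total_score(ev_assign(c("4A", "4A"), 0.45)), "4A")
  rg <- load_rubric("gain")
  expect_error(total_score(ev_assign(c("2J", "2K"), c(0, 0.45)), rg),
               "exclusive")
  # permutation invariance
  set.seed(5)
  a <- ev_assign(c("4A", "4B", "4C", "4O"), c(0.45, 0.3, 0.15, -1))
  for (i in 1:10) {
    expect_equal(total_score(a[sample(nrow(a)), ]), total_score(a))
  }
})

test_that("classify maps totals through the five-tier thresholds", {
  rb <- load_rubric("loss")
  expect_equal(classify(0, rb), "VUS")
  expect_equal(classify(1, rb), "P")
  expect_equal(classify(0.45, rb), "VUS")
  expect_equal(classify(0.99, rb), "P")
  expect_equal(classify(0.9, rb), "LP")
  expect_equal(classify(-0.9, rb), "LB")
  expect_equal(classify(-0.99, rb), "B")
  # monotone step function: higher total never more benign
  set.seed(8)
  totals <- sort(runif(300, -2, 2))
  ranks <- match(classify(totals, rb), classification_levels())
  expect_true(all(diff(ranks) >= 0))
})

test_that("no single default category reaches P or B on its own", {
  for (dt in c("loss", "gain")) {
    rb <- load_rubric(dt)
    cls <- classify(rb$categories$default_points, rb)
    hits <- cls %in% c("P", "B") &
      abs(rb$categories$default_points) < rb$thresholds$p_min
    expect_false(any(hits), info = dt)
  }
})

test_that("score_cnv enforces rubric/CNV type match and reports", {
  rl <- load_rubric("loss")
  rg <- load_rubric("gain")
  loss <- one_cnv("1", 1e6, 2e6, "loss")
  gain <- one_cnv("1", 1e6, 2e6, "gain", id = "g1")
  empty <- score_cnv(loss, NULL, rl)
  expect_equal(empty$total_points, 0)
  expect_equal(empty$classification, "VUS")
  s <- score_cnv(gain, ev_assign("2K", 0.45), rg)
  expect_equal(s$classification, "VUS")
  expect_error(score_cnv(gain, NULL, rl), "rubric is for")
  full <- score_cnv(loss, ev_assign(c("2A", "4A"), c(1, 0.45)), rl)
  expect_equal(full$total_points, 1.45)
  expect_equal(full$classification, "P")
  expect_equal(sum(full$assignments$points), full$total_points,
               tolerance = 1e-9)
})
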