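test_that("fatty-acid labels parse and sort canonically", {
  p <- parse_fa_label(c("12:0", "18:3n3", "18:3n-6", "24:1"))
  expect_equal(p$label, c("12:0", "18:3n3", "18:3n6", "24:1"))
  expect_equal(p$carbon, c(12L, 18L, 18L, 24L))
  expect_equal(sort_fa(c("18:1", "12:0", "18:3n6", "18:3n3", "16:0", "18:0")),
               c("12:0", "16:0", "18:0", "18:1", "18:3n3", "18:3n6"))
  expect_error(parse_fa_label("palmitic"), "unparseable")
  expect_error(as_signature(c("16:0" = -1)), "negative")
  expect_error(as_signature(c("16:0" = 0)), "no positive")
  expect_error(as_signature(c("16:0" = 1, "16:0" = 2)), "duplicate")
})

test_that("mean_signature averages replicates per fatty acid", {
  set1 <- source_sample_set("grass", "low", list(
    c("16:0" = 10, "18:1" = 20), c("16:0" = 20, "18:1" = 40)))
  expect_equal(unname(mean_signature(set1)), c(15, 30))
  single <- source_sample_set("grass", "low", list(c("16:0" = 7, "18:1" = 3)))
  expect_equal(mean_signature(single), c("16:0" = 7, "18:1" = 3))
  # replicates drawn around a known mean land near it (8 reps, cv 3%)
  set.seed(42)
  mu <- c("16:0" = 200, "18:1" = 100)
  reps <- lapply(1:8, function(i) mu * (1 + rnorm(2, 0, 0.03)))
  est <- mean_signature(source_sample_set("grass", "low", reps))
  se <- mu * 0.03 / sqrt(8)
  expect_true(all(abs(est - mu) < 3 * se))
})

test_that("cv_profile computes sample sd/mean and flags zero-mean acids", {
  # two replicates placed mean +/- sd around 61.7 with sd 13.9
  grass <- source_sample_set("g", "low", list(
    c("12:0" = 61.7 - 13.9, "13:0" = 0), c("12:0" = 61.7 + 13.9, "13:0" = 0)))
  cv <- cv_profile(grass)
  expect_equal(unname(cv["12:0"]), sd(c(47.8, 75.6)) / 61.7, tolerance = 1e-12)
  expect_true(is.na(cv["13:0"]))
  same <- source_sample_set("g", "low", list(c("12:0" = 5), c("12:0" = 5)))
  expect_equal(unname(cv_profile(same)), 0)
  expect_error(cv_profile(source_sample_set("g", "low", list(c("12:0" = 5)))),
               "cv undefined")
})

test_that("high-abundance shared-FA rule selects the canonical ten acids", {
  fat <- example_fat_means()
  sel <- select_shared_fas(fat, threshold = 5)
  expect_identical(sel, c("12:0", "14:0", "15:0", "16:0", "16:1", "17:0",
                          "18:0", "18:1", "18:2", "18:3n3"))
  # 20:1 averages 4.6 across species and is excluded at 5.0
  expect_false("20:1" %in% sel)
  expect_equal(mean(c(fat$pika["20:1"], fat$mouse["20:1"])), 4.6)
  # threshold 0 keeps every acid with positive cross-species mean
  sel0 <- select_shared_fas(fat, threshold = 0)
  allfa <- rownames(zero_fill(fat))
  expect_setequal(sel0, allfa[rowMeans(zero_fill(fat)) > 0])
  expect_error(select_shared_fas(fat, threshold = 1e6), "no FAs pass")
})

test_that("raising the selection threshold never adds a fatty acid", {
  fat <- example_fat_means()
  thresholds <- c(0, 1, 2, 5, 10, 50, 100)
  sets <- lapply(thresholds, function(th) select_shared_fas(fat, th))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("restrict_and_rescale preserves composition and hits the target total", {
  s <- c("12:0" = 10, "14:0" = 30, "16:0" = 60)
  r <- restrict_and_rescale(s, c("12:0", "14:0"), 100)
  expect_equal(unname(r), c(25, 75))
  expect_equal(restrict_and_rescale(s, names(s), sum(s)), s)
  # the bundled pika mean restricted to the ten fitting acids
  sel <- select_shared_fas(example_fat_means(), 5)
  r2 <- restrict_and_rescale(example_fat_means()$pika, sel, 1000)
  expect_equal(sum(r2), 1000, tolerance = 1e-9)
  expect_equal(unname(r2["16:0"]), 249.9 * 1000 / 985.7, tolerance = 1e-9)
  expect_error(restrict_and_rescale(s, "18:0", 100), "zero total")
  # property: random subsets always sum to the target
  set.seed(7)
  for (i in 1:20) {
    sub <- sample(names(s), sample(2:3, 1))
    out <- restrict_and_rescale(s, sub, 500)
    expect_equal(sum(out), 500, tolerance = 1e-9)
    expect_equal(unname(out / sum(out) * sum(s[names(out)])),
                 unname(s[names(out)]), tolerance = 1e-9)
  }
})

test_that("signature tables survive a write/read round trip", {
  lib <- source_library(list(
    source_sample_set("grass", "low", list(c("12:0" = 61.7, "16:0" = 285),
                                           c("12:0" = 60.1, "16:0" = 281.2))),
    source_sample_set("feces", "low", list(c("12:0" = 90.5, "13:0" = 12.4,
                                             "16:0" = 258.7)))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_signature_table(lib, path)
  lib2 <- read_signature_table(path, kind = "source")
  expect_setequal(names(lib2$sets), names(lib$sets))
  for (key in names(lib$sets)) {
    a <- lib$sets[[key]]$replicates
    b <- lib2$sets[[key]]$replicates
    # zero-filling on read unions labels across all samples in the file
    expect_equal(b[rownames(a), , drop = FALSE],
                 a, ignore_attr = "dimnames")
    expect_true(all(b[setdiff(rownames(b), rownames(a)), ] == 0))
  }
  consumers <- list(consumer_sample("F1", "pika", "low",
                                    c("16:0" = 249.9, "18:1" = 104.8)))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_signature_table(consumers, path2)
  back <- read_signature_table(path2, kind = "consumer")
  expect_identical(back[[1]]$fat, consumers[[1]]$fat)
  expect_identical(back[[1]]$site, "low")
})

test_that("malformed signature tables are rejected with informative errors", {
  bad_neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,site,fa_label,ug_per_mg",
               "s1,grass,low,12:0,61.7", "s1,grass,low,16:0,-1.0"), bad_neg)
  expect_error(read_signature_table(bad_neg, "source"), "negative.*16:0")
  bad_label <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,site,fa_label,ug_per_mg",
               "s1,grass,low,palmitate,61.7"), bad_label)
  expect_error(read_signature_table(bad_label, "source"), "unparseable")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("sample_id,group,site,fa_label,ug_per_mg", empty)
  expect_error(read_signature_table(empty, "source"), "no samples")
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,site,fa_label,ug_per_mg",
               "s1,grass,low,12:0,61.7", "s1,grass,low,12:0,60.0"), dup)
  expect_error(read_signature_table(dup, "source"), "duplicate")
})

test_that("wide-format tables parse like long-format ones", {
  wide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,group,site,12:0,16:0",
               "s1,grass,low,61.7,285",
               "s2,grass,low,51,218.9"), wide)
  lib <- read_signature_table(wide, "source")
  expect_equal(unname(mean_signature(lib$sets[[1]])), c(56.35, 251.95))
})
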