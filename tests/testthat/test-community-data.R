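test_that("TSV and BIOM round-trips reproduce the table exactly", {
  tab <- make_table(rbind(c(1, 2, 0), c(0, 5, 3)))
  for (fmt in c("tsv", "biom-json")) {
    path <- withr::local_tempfile(fileext = if (fmt == "tsv") ".tsv" else ".biom")
    write_abundance_table(tab, path, format = fmt)
    back <- read_abundance_table(path, format = fmt)
    expect_identical(unclass(back), unclass(tab))
  }
  # transposed TSV layout, auto-detected via the sample_id header
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(tab, path, samples_as_rows = TRUE)
  expect_identical(unclass(read_abundance_table(path)), unclass(tab))
  # 1x1 table: the file carries the single count
  p1 <- withr::local_tempfile(fileext = ".tsv")
  write_abundance_table(make_table(matrix(7, 1, 1)), p1)
  expect_match(paste(readLines(p1), collapse = "\n"), "7")
})

test_that("table validation raises distinct named errors", {
  expect_error(read_abundance_table("no/such/file.tsv"),
               class = "passar_missing_file")
  m <- matrix(1:4, 2, dimnames = list(c("a", "a"), c("t1", "t2")))
  expect_error(abundance_table(m), class = "passar_duplicate_ids")
  expect_error(make_table(rbind(c(-1, 2))), class = "passar_bad_counts")
  expect_error(make_table(rbind(c(1.5, 2))), class = "passar_bad_counts")
  expect_error(abundance_table(matrix(1, 1, 1)), class = "passar_missing_ids")
  expect_error(make_table(matrix(0, 1, 1), samples = "s1", taxa = "t1") |>
                 abundance_table(require_positive_samples = TRUE),
               class = "passar_empty_sample")
  # duplicated sample ID in a TSV file
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tt1", "a\t1", "a\t2"), path)
  expect_error(read_abundance_table(path), class = "passar_duplicate_ids")
})

test_that("abundance classes follow pooled relative abundance with closed boundaries", {
  # hand arithmetic: totals [10000, 50, 5, 1] over grand total 10056
  tab <- make_table(rbind(c(10000, 50, 5, 1)))
  cls <- classify_abundance(tab)
  expect_equal(as.character(cls), c("abundant", "abundant", "moderate", "rare"))
  # 0.15% total relative abundance is abundant
  tab2 <- make_table(rbind(c(15, 9985)))
  expect_equal(as.character(classify_abundance(tab2)[1]), "abundant")
  # single-taxon table: p = 1, abundant
  expect_equal(as.character(classify_abundance(make_table(matrix(5, 1, 1)))),
               "abundant")
  # exact boundary equality goes to moderate (both thresholds)
  tab3 <- make_table(rbind(c(10, 1, 9989)))  # p = 0.001 and 0.0001 exactly
  cls3 <- classify_abundance(tab3)
  expect_equal(as.character(cls3)[1:2], c("moderate", "moderate"))
  expect_error(classify_abundance(make_table(matrix(0, 1, 1))),
               class = "passar_empty_table")
})

test_that("class partition and threshold monotonicity hold on random tables", {
  for (seed in 1:5) {
    tab <- random_table(4, 60, lambda = 1.2, seed = seed)
    cls <- classify_abundance(tab)
    expect_equal(sum(base::table(cls)), ncol(tab))
    tight <- classify_abundance(tab, class_thresholds(0.01, 0.0001))
    expect_lte(sum(tight == "abundant"), sum(cls == "abundant"))
    low <- classify_abundance(tab, class_thresholds(0.001, 0.00001))
    expect_lte(sum(low == "rare"), sum(cls == "rare"))
  }
  expect_error(class_thresholds(0.0001, 0.001), class = "passar_bad_thresholds")
})

test_that("alpha diversity matches closed forms and the vegan oracle", {
  uni <- make_table(matrix(1, 1, 10))
  # count-1-each sample is all singletons: ACE warning asserted elsewhere
  a <- suppressWarnings(alpha_diversity(uni))
  expect_equal(a$richness, 10)
  expect_equal(a$shannon, log(10))
  expect_equal(a$simpson, 0.9)
  # hand arithmetic on p = 0.5 / 0.3 / 0.2
  b <- alpha_diversity(make_table(rbind(c(5, 3, 2))))
  expect_equal(b$shannon, -(0.5 * log(0.5) + 0.3 * log(0.3) + 0.2 * log(0.2)))
  expect_equal(b$shannon, 1.0297, tolerance = 1e-4)
  expect_equal(b$simpson, 0.62)
  # vegan as independent oracle for Shannon, Simpson and ACE
  tab <- random_table(5, 80, lambda = 4, seed = 42)
  mine <- alpha_diversity(tab)
  expect_equal(mine$shannon, unname(vegan::diversity(unclass(tab))),
               tolerance = 1e-12)
  expect_equal(mine$simpson,
               unname(vegan::diversity(unclass(tab), "simpson")),
               tolerance = 1e-12)
  ests <- vegan::estimateR(unclass(tab))
  expect_equal(mine$ace, unname(ests["S.ACE", ]), tolerance = 1e-8)
  expect_true(all(mine$ace >= mine$richness))
  expect_error(alpha_diversity(abundance_table(
    rbind(s1 = c(t1 = 0, t2 = 0)))), class = "passar_empty_sample")
})

test_that("ACE on an all-singleton sample diverges with a warning", {
  tab <- make_table(matrix(1, 1, 12))
  expect_warning(a <- alpha_diversity(tab), "ACE undefined")
  expect_gte(a$ace, a$richness)
})

test_that("shannon stays within [0, ln(richness)] on random samples", {
  for (seed in 1:10) {
    tab <- random_table(1, 30, lambda = 2, seed = 100 + seed)
    a <- alpha_diversity(tab)
    expect_gte(a$shannon, 0)
    expect_lte(a$shannon, log(a$richness) + 1e-12)
  }
})

test_that("rank abundance sorts by abundance with lexicographic tie-break", {
  tab <- make_table(rbind(c(2, 1, 1)), taxa = c("x", "b", "a"))
  ra <- rank_abundance(tab, "s1")
  expect_equal(ra$rank, 1:3)
  expect_equal(ra$taxon_id, c("x", "a", "b"))  # tie between a/b: a first
  expect_equal(ra$relative_abundance, c(0.5, 0.25, 0.25))
  expect_equal(sum(ra$relative_abundance), 1)
  one <- rank_abundance(make_table(rbind(c(0, 4))), "s1")
  expect_equal(nrow(one), 1)
  expect_equal(one$relative_abundance, 1)
  expect_error(rank_abundance(tab, "nope"), class = "passar_unknown_sample")
})

test_that("sample areas validate, convert units, and round-trip", {
  a <- sample_areas(c(tw1 = 0.36, tw2 = 0.36))
  expect_equal(as.numeric(convert_area_unit(a, "cm2")), c(3600, 3600))
  expect_equal(as.numeric(convert_area_unit(convert_area_unit(a, "cm2"), "m2")),
               c(0.36, 0.36))
  expect_error(sample_areas(c(tw1 = -1)), class = "passar_bad_area")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sample_areas(a, path)
  expect_equal(as.numeric(read_sample_areas(path)), as.numeric(a))
})
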