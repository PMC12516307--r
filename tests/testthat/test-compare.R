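test_that("comparing an annotation with itself reports no non-equal entries", {
  a <- base_full_annotation()
  rep <- compare_annotations(a, a)
  expect_identical(rep$n_differs, 0L)
  expect_identical(rep$n_only_first, 0L)
  expect_identical(rep$n_only_second, 0L)
  expect_identical(rep$n_equal, nrow(rep$entries))
})

test_that("k injected field edits are recovered as exactly the k edited paths", {
  edits <- comparison_edits()
  for (k in 1:5) {
    b <- unclass(base_full_annotation())
    for (path in names(edits)[1:k]) b <- edits[[path]](b)
    rep <- compare_annotations(base_full_annotation(), b)
    expect_setequal(rep$entries$path[rep$entries$status == "differs"],
                    names(edits)[1:k])
    expect_identical(rep$n_differs, k)
  }
})

test_that("an optional section in only one study yields only_in_* for its leaves", {
  a <- base_full_annotation()
  b <- unclass(base_full_annotation())
  b["lab_verification"] <- list(NULL)
  rep <- compare_annotations(a, b)
  lv <- rep$entries[startsWith(rep$entries$path, "lab_verification"), ]
  expect_identical(unique(lv$status), "only_in_first")
  expect_identical(nrow(lv), 2L)
  swapped <- compare_annotations(b, a)
  lv2 <- swapped$entries[startsWith(swapped$entries$path, "lab_verification"), ]
  expect_identical(unique(lv2$status), "only_in_second")
})

test_that("the report partitions all schema leaves and is symmetric", {
  a <- generate_annotation(fixture_config(seed = 21, p_optional = 1))
  b <- generate_annotation(fixture_config(seed = 22, p_optional = 0))
  rep <- compare_annotations(a, b)
  expect_identical(rep$n_equal + rep$n_differs + rep$n_only_first +
                     rep$n_only_second, nrow(rep$entries))
  expect_identical(sort(rep$entries$path), sort(unique(rep$entries$path)))
  rev <- compare_annotations(b, a)
  expect_identical(rev$n_differs, rep$n_differs)
  expect_identical(rev$n_equal, rep$n_equal)
  expect_identical(rev$n_only_first, rep$n_only_second)
  expect_identical(rev$n_only_second, rep$n_only_first)
  expect_setequal(rev$entries$path[rev$entries$status == "differs"],
                  rep$entries$path[rep$entries$status == "differs"])
})

test_that("a custom answer never equals a predefined term with the same label", {
  a <- unclass(minimal_annotation())
  b <- unclass(minimal_annotation())
  b$evolutionary_information$age_inference <- dnf_custom("synteny_based")
  rep <- compare_annotations(a, b)
  row <- rep$entries[rep$entries$path == "evolutionary_information.age_inference", ]
  expect_identical(row$status, "differs")
  expect_match(row$value_second, "custom")
})

test_that("list-valued fields compare as sets of canonical values", {
  a <- unclass(base_full_annotation())
  b <- unclass(base_full_annotation())
  b$input_data$candidate_sources <- rev(b$input_data$candidate_sources)
  rep <- compare_annotations(a, b)
  expect_identical(rep$n_differs, 0L)
})

test_that("the two render modes partition the report's entries and end with counts", {
  edits <- comparison_edits()
  b <- edits[[1]](unclass(base_full_annotation()))
  rep <- compare_annotations(base_full_annotation(), b)
  diff_txt <- render_report(rep, "differences")
  sim_txt <- render_report(rep, "similarities")
  expect_match(diff_txt, "homology_criterion")
  expect_no_match(sim_txt, "homology_criterion:")
  expect_match(diff_txt, "counts: equal=12 differing=1 only_in_first=0 only_in_second=0")
  expect_match(sim_txt, "counts: equal=12 differing=1")
  # stable across runs
  expect_identical(render_report(rep, "differences"), diff_txt)
  # one section heading and one entry line for the single difference
  body <- strsplit(diff_txt, "\n")[[1]]
  expect_identical(sum(grepl("^\\[", body)), 1L)
  expect_identical(sum(grepl("<>", body, fixed = TRUE)), 1L)
})

test_that("zero-difference reports say so in differences mode", {
  rep <- compare_annotations(minimal_annotation(), minimal_annotation())
  txt <- render_report(rep, "differences")
  expect_match(txt, "no methodological differences")
  expect_match(txt, "differing=0")
})

test_that("a major format version mismatch is flagged prominently", {
  a <- unclass(minimal_annotation())
  b <- unclass(minimal_annotation())
  b$format_version <- "1.4"
  expect_false(compare_annotations(a, b)$version_mismatch)
  b$format_version <- "2.0"
  rep <- compare_annotations(a, b)
  expect_true(rep$version_mismatch)
  expect_match(render_report(rep, "differences"),
               "WARNING: major format version mismatch")
})
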