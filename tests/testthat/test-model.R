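test_that("a complete annotation validates cleanly and the root has six section slots", {
  res <- validate_annotation(base_full_annotation())
  expect_true(res$valid)
  expect_identical(nrow(res$violations), 0L)
  expect_length(dnf_sections(), 6L)
  expect_identical(dnf_sections(required_only = TRUE),
                   c("input_data", "evolutionary_information", "homology_filter"))
  # every annotation object exposes all six slots, present or NULL
  expect_true(all(dnf_sections() %in% names(base_full_annotation())))
  expect_true(all(dnf_sections() %in% names(minimal_annotation())))
})

test_that("removing a required section yields exactly one violation at that path", {
  a <- unclass(base_full_annotation())
  a["homology_filter"] <- list(NULL)
  res <- validate_annotation(a)
  expect_false(res$valid)
  expect_identical(res$violations$path, "homology_filter")
  expect_match(res$violations$message, "required section missing")
})

test_that("the non-coding homolog consistency rule is enforced on its own", {
  a <- unclass(base_full_annotation())
  a$non_coding_homologs$detection_methods <- list()
  res <- validate_annotation(a)
  expect_false(res$valid)
  expect_identical(res$violations$path, "non_coding_homologs.detection_methods")
})

test_that("every single-invariant mutation is rejected with a violation at the mutated field", {
  muts <- invariant_mutations()
  for (path in names(muts)) {
    mutated <- muts[[path]](unclass(base_full_annotation()))
    res <- validate_annotation(mutated)
    expect_false(res$valid, label = paste("mutation", path, "valid"))
    expect_true(any(startsWith(res$violations$path, path)),
                label = paste("violation path for", path, "got:",
                              paste(res$violations$path, collapse = ", ")))
  }
})

test_that("validator agrees with an independent brute-force invariant oracle", {
  # valid fixtures: both report nothing
  for (s in 1:40) {
    a <- generate_annotation(fixture_config(seed = s, adversarial_text = TRUE))
    expect_true(validate_annotation(a)$valid)
    expect_length(oracle_violation_paths(a), 0L)
  }
  # mutated fixtures: the oracle's violated paths are all reported
  muts <- invariant_mutations()
  for (path in names(muts)) {
    mutated <- muts[[path]](unclass(base_full_annotation()))
    got <- validate_annotation(mutated)$violations$path
    for (p in oracle_violation_paths(mutated))
      expect_true(any(startsWith(got, p) | startsWith(p, got)),
                  label = paste("oracle path", p, "reported"))
  }
})

test_that("all problems are reported together, not only the first", {
  a <- unclass(base_full_annotation())
  a["input_data"] <- list(NULL)
  a$evolutionary_information$outgroup_count <- -2L
  a$non_coding_homologs$detection_methods <- list()
  res <- validate_annotation(a)
  expect_gte(nrow(res$violations), 3L)
  expect_setequal(
    intersect(res$violations$path,
              c("input_data", "evolutionary_information.outgroup_count",
                "non_coding_homologs.detection_methods")),
    c("input_data", "evolutionary_information.outgroup_count",
      "non_coding_homologs.detection_methods"))
})

test_that("canonicalize sorts, trims and is an idempotent validity-preserving map", {
  a <- denofo_annotation(
    dnf_input_data(list(dnf_predefined("candidate_sources", "transcriptome_assembly"),
                        dnf_custom("  ribo-seq harringtonine  "),
                        dnf_predefined("candidate_sources", "genome_annotation"))),
    dnf_evolutionary_information("phylostratigraphy"),
    dnf_homology_filter(dnf_tool("blast"), "no_hit_in_any_outgroup"),
    hyperlinks = dnf_hyperlinks(c("https://b.org", "10.1/x", "https://a.org")))
  ca <- canonicalize(a)
  # predefined terms first (sorted by term id), customs after (sorted by text)
  expect_identical(
    vapply(ca$input_data$candidate_sources, function(x) x$kind, ""),
    c("predefined", "predefined", "custom"))
  expect_identical(ca$input_data$candidate_sources[[1]]$term, "genome_annotation")
  expect_identical(ca$input_data$candidate_sources[[3]]$text,
                   "ribo-seq harringtonine")
  # links sorted by (kind, value)
  expect_identical(vapply(ca$hyperlinks$links, `[[`, "", "kind"),
                   c("doi", "url", "url"))
  expect_identical(ca$hyperlinks$links[[2]]$value, "https://a.org")
  # idempotence and fixed point on already-canonical input
  expect_identical(canonicalize(ca), ca)
  expect_true(validate_annotation(ca)$valid)
  for (s in 1:25) {
    f <- generate_annotation(fixture_config(seed = s, adversarial_text = TRUE))
    cf <- canonicalize(f)
    expect_identical(canonicalize(cf), cf)
    expect_true(validate_annotation(cf)$valid)
  }
})

test_that("invalid input to canonicalize signals a validation error", {
  a <- unclass(minimal_annotation())
  a["input_data"] <- list(NULL)
  expect_error(canonicalize(a), class = "dnf_validation_error")
})
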