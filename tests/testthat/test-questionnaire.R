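answer_through <- function(st, values) {
  for (v in values) st <- answer_current(st, v)
  st
}

# Minimal complete answer run: declines every optional section.
minimal_run <- function() {
  answer_through(build_questionnaire(), list(
    "genome_annotation",        # candidate_sources
    NULL,                       # orf_definition (skip)
    NULL,                       # minimum_orf_length (skip)
    "phylostratigraphy",        # age_inference
    NULL,                       # outgroup_count (skip)
    NULL,                       # phylogeny_source (skip)
    "blast",                    # searches
    "no_hit_in_any_outgroup",   # homology_criterion
    FALSE, FALSE, FALSE))       # decline all optional sections
}

test_that("questions cover the schema in section order with branch guards", {
  st <- build_questionnaire()
  q1 <- current_question(st)
  expect_identical(q1$target_path, "input_data.candidate_sources")
  targets <- vapply(st$questions, `[[`, "", "target_path")
  leaf_targets <- targets[!vapply(st$questions, `[[`, TRUE, "gate")]
  expect_setequal(leaf_targets, c(
    "input_data.candidate_sources", "input_data.orf_definition",
    "input_data.minimum_orf_length_codons",
    "evolutionary_information.age_inference",
    "evolutionary_information.outgroup_count",
    "evolutionary_information.phylogeny_source",
    "homology_filter.searches", "homology_filter.homology_criterion",
    "non_coding_homologs.required_for_classification",
    "non_coding_homologs.detection_methods",
    "lab_verification.transcription_evidence",
    "lab_verification.translation_evidence", "hyperlinks.links"))
  # required-section questions carry no applicability guard
  for (q in st$questions) {
    sec <- sub("\\..*$", "", q$target_path)
    if (sec %in% dnf_sections(required_only = TRUE))
      expect_null(q$applicable_when)
  }
  expect_error(build_questionnaire("7.0"), class = "dnf_version_error")
})

test_that("declining a gate skips the section and yields a valid annotation without it", {
  ann <- finalize(minimal_run())
  expect_true(validate_annotation(ann)$valid)
  expect_null(ann$non_coding_homologs)
  expect_null(ann$lab_verification)
  expect_null(ann$hyperlinks)
})

test_that("required_for_classification = FALSE skips the detection-methods question", {
  st <- answer_through(build_questionnaire(), list(
    "genome_annotation", NULL, NULL, "phylostratigraphy", NULL, NULL,
    "blast", "no_hit_in_any_outgroup",
    TRUE,    # include non-coding homolog section
    FALSE))  # not required for classification
  expect_identical(current_question(st)$id, "include_lab_verification")
  st <- answer_through(st, list(FALSE, FALSE))
  ann <- finalize(st)
  expect_false(ann$non_coding_homologs$required_for_classification)
  expect_length(ann$non_coding_homologs$detection_methods, 0L)
})

test_that("custom text at a choice question becomes a custom value", {
  st <- build_questionnaire()
  st <- answer_current(st, "my bespoke source")
  ann_part <- st$answers$candidate_sources[[1]]
  expect_identical(ann_part$kind, "custom")
  expect_identical(ann_part$text, "my bespoke source")
})

test_that("navigation: go_back revisits, re-answering replaces, first question is a wall", {
  st <- build_questionnaire()
  expect_error(go_back(st), class = "dnf_navigation_error")
  st <- answer_current(st, "genome_annotation")
  before <- st
  st <- go_back(st)
  expect_identical(current_question(st)$id, "candidate_sources")
  st <- answer_current(st, "genome_annotation")
  expect_identical(st$answers, before$answers)
  st <- answer_current(st, "transcriptome_assembly")  # now at orf_definition? no: cursor moved
  # re-answer candidate_sources with a different value
  st2 <- go_back(go_back(st))
  st2 <- answer_current(st2, "mass_spectrometry")
  expect_identical(st2$answers$candidate_sources[[1]]$term, "mass_spectrometry")
})

test_that("changing a gate answer discards downstream answers that became inapplicable", {
  st <- answer_through(build_questionnaire(), list(
    "genome_annotation", NULL, NULL, "phylostratigraphy", NULL, NULL,
    "blast", "no_hit_in_any_outgroup",
    TRUE, TRUE, "synteny_alignment"))
  expect_true("detection_methods" %in% names(st$answers))
  # walk back to the gate and decline the section
  while (current_question(st)$id != "include_non_coding_homologs")
    st <- go_back(st)
  st <- answer_current(st, FALSE)
  expect_false("detection_methods" %in% names(st$answers))
  expect_false("required_for_classification" %in% names(st$answers))
  st <- answer_through(st, list(FALSE, FALSE))
  expect_null(finalize(st)$non_coding_homologs)
})

test_that("type and range violations are rejected with input errors", {
  st <- build_questionnaire()
  expect_error(answer_current(st, 42), class = "dnf_input_error")
  st <- answer_through(st, list("genome_annotation", NULL))
  expect_error(answer_current(st, -5), class = "dnf_input_error")   # min codons >= 1
  expect_error(answer_current(st, 2.5), class = "dnf_input_error")
})

test_that("finalize on an incomplete state names every unanswered required question", {
  st <- answer_through(build_questionnaire(), list(
    "genome_annotation", NULL, NULL, "phylostratigraphy", NULL, NULL))
  err <- expect_error(finalize(st), class = "dnf_completeness_error")
  expect_match(conditionMessage(err), "homology")
  expect_gte(length(err$missing), 2L)
})

test_that("random answer-sequence fuzzing never finalizes into an invalid annotation", {
  for (s in 1:60) {
    st <- fuzz_questionnaire(s)
    if (is.null(current_question(st))) {
      ann <- finalize(st)
      expect_true(validate_annotation(ann)$valid, label = paste("seed", s))
      expect_identical(ann, canonicalize(ann))
    }
  }
})
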