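# Schema structure shared by validation, comparison and the questionnaire.
# The root record has exactly six section slots; the first three are
# required in every annotation, the rest document supplementary evidence.

#' Section slots of a DeNoFo annotation
#'
#' @param required_only If `TRUE`, return only the sections every valid
#'   annotation must carry.
#' @return Character vector of section names in their fixed document order.
#' @examples
#' dnf_sections()
#' @export
dnf_sections <- function(required_only = FALSE) {
  sec <- c("input_data", "evolutionary_information", "homology_filter",
           "non_coding_homologs", "lab_verification", "hyperlinks")
  if (required_only) sec[1:3] else sec
}

REQUIRED_SECTIONS <- c("input_data", "evolutionary_information", "homology_filter")

# Leaf fields of the schema, one row per leaf, in document order.
#   kind: how the leaf is validated / compared / asked about.
#   vocabulary: controlled vocabulary for choice leaves ("" otherwise).
schema_leaves <- function() {
  data.frame(
    path = c(
      "input_data.candidate_sources",
      "input_data.orf_definition",
      "input_data.minimum_orf_length_codons",
      "evolutionary_information.age_inference",
      "evolutionary_information.outgroup_count",
      "evolutionary_information.phylogeny_source",
      "homology_filter.searches",
      "homology_filter.homology_criterion",
      "non_coding_homologs.required_for_classification",
      "non_coding_homologs.detection_methods",
      "lab_verification.transcription_evidence",
      "lab_verification.translation_evidence",
      "hyperlinks.links"
    ),
    kind = c(
      "choice_list", "choice", "integer",
      "choice", "integer", "choice",
      "tool_list", "choice",
      "boolean", "choice_list",
      "choice_list", "choice_list",
      "link_list"
    ),
    vocabulary = c(
      "candidate_sources", "orf_definition", "",
      "age_inference", "", "phylogeny_source",
      "homology_tools", "homology_criterion",
      "", "noncoding_detection",
      "transcription_evidence", "translation_evidence",
      ""
    ),
    optional = c(
      FALSE, TRUE, TRUE,
      FALSE, TRUE, TRUE,
      FALSE, FALSE,
      FALSE, TRUE,
      FALSE, FALSE,
      FALSE
    ),
    stringsAsFactors = FALSE
  )
}

leaf_section <- function(path) sub("\\..*$", "", path)
leaf_field <- function(path) sub("^[^.]*\\.", "", path)
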