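#' Predefined or custom answer values
#'
#' Most fields of a DeNoFo annotation take either a term from a controlled
#' vocabulary (so that studies remain machine-comparable) or a free-text
#' custom answer (so that no methodology is forced into an ill-fitting
#' category). `dnf_predefined()` builds the former, `dnf_custom()` the
#' latter. Custom text may contain any Unicode character — including `;`,
#' `=`, `%` and newlines — and every serialization in the package preserves
#' it byte-for-byte apart from trimming surrounding whitespace.
#'
#' @param vocabulary Vocabulary id, see [dnf_vocabularies()].
#' @param term Term id within that vocabulary.
#' @param text Non-empty free-form answer text.
#' @return A `dnf_choice` value.
#' @examples
#' dnf_predefined("age_inference", "phylostratigraphy")
#' dnf_custom("syntenic anchoring with custom HMMs")
#' @export
dnf_predefined <- function(vocabulary, term) {
  structure(list(kind = "predefined", vocabulary = vocabulary, term = term),
            class = "dnf_choice")
}

#' @rdname dnf_predefined
#' @export
dnf_custom <- function(text) {
  structure(list(kind = "custom", text = text), class = "dnf_choice")
}

is_choice <- function(x) {
  is.list(x) && !is.null(x$kind) && x$kind %in% c("predefined", "custom")
}

# Coerce a character term (or list of them) into predefined choices of the
# given vocabulary; pass dnf_choice values through. Constructor sugar only —
# validation never coerces.
as_choice <- function(x, vocabulary) {
  if (is_choice(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(dnf_predefined(vocabulary, x))
  x
}

as_choice_list <- function(x, vocabulary) {
  if (is.character(x)) x <- as.list(x)
  if (is_choice(x)) x <- list(x)
  lapply(x, as_choice, vocabulary = vocabulary)
}

#' Homology search invocation
#'
#' One run of a homology/similarity search tool used to establish the
#' absence of detectable homologs, with its database and thresholds.
#'
#' @param tool Tool name (a `homology_tools` vocabulary term, a
#'   [dnf_custom()] value for unlisted tools, or a `dnf_choice`).
#' @param database Optional free-text database name and version.
#' @param evalue_threshold Optional E-value cutoff (> 0).
#' @param coverage_threshold Optional query/subject coverage cutoff in
#'   `[0, 1]`.
#' @return A `dnf_tool` value.
#' @examples
#' dnf_tool("blast", database = "nr 2024-01", evalue_threshold = 1e-5)
#' @export
dnf_tool <- function(tool, database = NULL, evalue_threshold = NULL,
                     coverage_threshold = NULL) {
  structure(list(tool = as_choice(tool, "homology_tools"),
                 database = database,
                 evalue_threshold = evalue_threshold,
                 coverage_threshold = coverage_threshold),
            class = "dnf_tool")
}

#' Hyperlink entry
#'
#' @param value The link text: a DOI of the form `10.<digits>/<suffix>` or a
#'   URL with an explicit scheme.
#' @param kind `"doi"` or `"url"`; guessed from `value` when omitted.
#' @return A link record `list(kind, value)`.
#' @examples
#' dnf_link("10.1000/example.42")
#' dnf_link("https://example.org/supplement")
#' @export
dnf_link <- function(value, kind = NULL) {
  if (is.null(kind)) kind <- if (grepl("^10\\.[0-9]+/", value)) "doi" else "url"
  list(kind = kind, value = value)
}

#' Section constructors for a DeNoFo annotation
#'
#' One constructor per section of the format. `dnf_input_data()`,
#' `dnf_evolutionary_information()` and `dnf_homology_filter()` build the
#' required sections; the remaining three are optional supplementary
#' evidence. Character arguments in choice positions are interpreted as
#' predefined terms of the field's vocabulary.
#'
#' @param candidate_sources Where candidate de novo genes/ORFs came from
#'   (vocabulary `candidate_sources`); at least one entry.
#' @param orf_definition Optional ORF calling convention (vocabulary
#'   `orf_definition`).
#' @param minimum_orf_length_codons Optional minimum ORF length, in codons.
#' @param age_inference How gene age / lineage specificity was inferred
#'   (vocabulary `age_inference`).
#' @param outgroup_count Optional number of outgroup species examined.
#' @param phylogeny_source Optional origin of the species phylogeny used
#'   (vocabulary `phylogeny_source`).
#' @param searches List of [dnf_tool()] invocations; at least one.
#' @param homology_criterion What counted as "no homolog" (vocabulary
#'   `homology_criterion`).
#' @param required_for_classification Whether a detectable non-coding
#'   homologous region in outgroups was required to call a gene de novo.
#' @param detection_methods Methods used to locate non-coding homologs
#'   (vocabulary `noncoding_detection`); required non-empty when
#'   `required_for_classification` is `TRUE`.
#' @param transcription_evidence,translation_evidence Evidence types
#'   (vocabularies `transcription_evidence` / `translation_evidence`); the
#'   term `none` may not co-occur with other terms.
#' @param links List of [dnf_link()] entries.
#' @return A named list for the corresponding section slot.
#' @name dnf_sections_constructors
NULL

#' @rdname dnf_sections_constructors
#' @export
dnf_input_data <- function(candidate_sources, orf_definition = NULL,
                           minimum_orf_length_codons = NULL) {
  list(candidate_sources = as_choice_list(candidate_sources, "candidate_sources"),
       orf_definition = if (!is.null(orf_definition))
         as_choice(orf_definition, "orf_definition"),
       minimum_orf_length_codons = minimum_orf_length_codons)
}

#' @rdname dnf_sections_constructors
#' @export
dnf_evolutionary_information <- function(age_inference, outgroup_count = NULL,
                                         phylogeny_source = NULL) {
  list(age_inference = as_choice(age_inference, "age_inference"),
       outgroup_count = outgroup_count,
       phylogeny_source = if (!is.null(phylogeny_source))
         as_choice(phylogeny_source, "phylogeny_source"))
}

#' @rdname dnf_sections_constructors
#' @export
dnf_homology_filter <- function(searches, homology_criterion) {
  if (inherits(searches, "dnf_tool")) searches <- list(searches)
  list(searches = searches,
       homology_criterion = as_choice(homology_criterion, "homology_criterion"))
}

#' @rdname dnf_sections_constructors
#' @export
dnf_non_coding_homologs <- function(required_for_classification,
                                    detection_methods = list()) {
  list(required_for_classification = required_for_classification,
       detection_methods = as_choice_list(detection_methods, "noncoding_detection"))
}

#' @rdname dnf_sections_constructors
#' @export
dnf_lab_verification <- function(transcription_evidence = list("none"),
                                 translation_evidence = list("none")) {
  list(transcription_evidence =
         as_choice_list(transcription_evidence, "transcription_evidence"),
       translation_evidence =
         as_choice_list(translation_evidence, "translation_evidence"))
}

#' @rdname dnf_sections_constructors
#' @export
dnf_hyperlinks <- function(links) {
  if (is.character(links)) links <- as.list(links)
  if (is.list(links) && !is.null(links$kind)) links <- list(links)
  list(links = lapply(links, function(l) if (is.character(l)) dnf_link(l) else l))
}

#' Assemble a DeNoFo annotation
#'
#' The root record of the format: one methodology description covering all
#' genes of a study. It always exposes six section slots (see
#' [dnf_sections()]); `input_data`, `evolutionary_information` and
#' `homology_filter` must be present, the other three may be `NULL`.
#'
#' @param input_data,evolutionary_information,homology_filter Required
#'   sections, from their constructors.
#' @param non_coding_homologs,lab_verification,hyperlinks Optional sections
#'   or `NULL`.
#' @param format_version Format version string; defaults to the version
#'   this package writes.
#' @param validate If `TRUE` (default), signal a validation error unless the
#'   assembled annotation is valid.
#' @return A `denofo_annotation` object.
#' @examples
#' ann <- denofo_annotation(
#'   input_data = dnf_input_data("transcriptome_assembly"),
#'   evolutionary_information = dnf_evolutionary_information("phylostratigraphy"),
#'   homology_filter = dnf_homology_filter(
#'     dnf_tool("blast", evalue_threshold = 1e-5),
#'     "no_hit_beyond_focal_clade"
#'   )
#' )
#' ann
#' @export
denofo_annotation <- function(input_data, evolutionary_information,
                              homology_filter, non_coding_homologs = NULL,
                              lab_verification = NULL, hyperlinks = NULL,
                              format_version = dnf_format_version(),
                              validate = TRUE) {
  ann <- structure(
    list(format_version = format_version,
         input_data = input_data,
         evolutionary_information = evolutionary_information,
         homology_filter = homology_filter,
         non_coding_homologs = non_coding_homologs,
         lab_verification = lab_verification,
         hyperlinks = hyperlinks),
    class = "denofo_annotation")
  if (validate) {
    res <- validate_annotation(ann)
    if (!res$valid) stop_validation(res$violations)
  }
  ann
}

#' @export
print.denofo_annotation <- function(x, ...) {
  cat("<denofo_annotation> format", x$format_version, "\n")
  for (sec in dnf_sections()) {
    if (is.null(x[[sec]])) {
      cat(sprintf("  %-25s (absent)\n", sec))
    } else {
      cat(sprintf("  %-25s %s\n", sec,
                  paste(names(x[[sec]])[!vapply(x[[sec]], is.null, TRUE)],
                        collapse = ", ")))
    }
  }
  invisible(x)
}

#' @export
format.dnf_choice <- function(x, ...) render_choice(x)

#' @export
print.dnf_choice <- function(x, ...) {
  cat(render_choice(x), "\n")
  invisible(x)
}

# Stable single-line rendering used by the comparator and reports.
render_choice <- function(x) {
  if (x$kind == "predefined") x$term
  else paste0("\"", gsub("\n", "\\\\n", x$text), "\" (custom)")
}

render_tool <- function(t) {
  parts <- render_choice(t$tool)
  if (!is.null(t$database)) parts <- paste0(parts, " db=", t$database)
  if (!is.null(t$evalue_threshold))
    parts <- paste0(parts, " evalue<=", num_to_str(t$evalue_threshold))
  if (!is.null(t$coverage_threshold))
    parts <- paste0(parts, " coverage>=", num_to_str(t$coverage_threshold))
  parts
}

render_link <- function(l) paste0(l$kind, ":", l$value)

# Exact decimal rendering: round-trips IEEE doubles through as.numeric().
num_to_str <- function(x) {
  s <- sprintf("%.17g", x)
  short <- sprintf("%.15g", x)
  if (as.numeric(short) == x) s <- short
  s
}
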