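#' Canonical form of an annotation
#'
#' Every codec in the package (dngf documents, shortcodes, carrier tokens)
#' serializes the canonical form, so that equal methodologies always produce
#' byte-identical output. Canonicalization trims surrounding whitespace from
#' custom answers, orders every list deterministically (predefined terms
#' before custom answers, each sorted bytewise; searches by their canonical
#' field rendering; links by kind then value), and normalizes numeric
#' storage. It is idempotent and preserves validity.
#'
#' @param ann A valid annotation (or annotation-shaped list).
#' @return A `denofo_annotation` in canonical form.
#' @examples
#' a <- denofo_annotation(
#'   dnf_input_data(c("transcriptome_assembly", "genome_annotation")),
#'   dnf_evolutionary_information("phylostratigraphy"),
#'   dnf_homology_filter(dnf_tool("blast"), "no_hit_in_any_outgroup")
#' )
#' ca <- canonicalize(a)
#' sapply(ca$input_data$candidate_sources, function(x) x$term)
#' identical(canonicalize(ca), ca)
#' @export
canonicalize <- function(ann) {
  res <- validate_annotation(ann)
  if (!res$valid) stop_validation(res$violations)

  out <- list(format_version = as.character(ann$format_version))
  out$input_data <- drop_null(list(
    candidate_sources = canon_choice_list(ann$input_data$candidate_sources),
    orf_definition = canon_choice_opt(ann$input_data$orf_definition),
    minimum_orf_length_codons =
      canon_int(ann$input_data$minimum_orf_length_codons)))
  out$evolutionary_information <- drop_null(list(
    age_inference = canon_choice(ann$evolutionary_information$age_inference),
    outgroup_count = canon_int(ann$evolutionary_information$outgroup_count),
    phylogeny_source =
      canon_choice_opt(ann$evolutionary_information$phylogeny_source)))
  out$homology_filter <- list(
    searches = canon_searches(ann$homology_filter$searches),
    homology_criterion = canon_choice(ann$homology_filter$homology_criterion))
  if (!is.null(ann$non_coding_homologs)) {
    out$non_coding_homologs <- list(
      required_for_classification =
        isTRUE(ann$non_coding_homologs$required_for_classification),
      detection_methods =
        canon_choice_list(ann$non_coding_homologs$detection_methods %||% list()))
  } else out["non_coding_homologs"] <- list(NULL)
  if (!is.null(ann$lab_verification)) {
    out$lab_verification <- list(
      transcription_evidence =
        canon_choice_list(ann$lab_verification$transcription_evidence %||% list()),
      translation_evidence =
        canon_choice_list(ann$lab_verification$translation_evidence %||% list()))
  } else out["lab_verification"] <- list(NULL)
  if (!is.null(ann$hyperlinks)) {
    out$hyperlinks <- list(links = canon_links(ann$hyperlinks$links))
  } else out["hyperlinks"] <- list(NULL)

  structure(out, class = "denofo_annotation")
}

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

canon_int <- function(x) if (is.null(x)) NULL else as.integer(x)

canon_choice <- function(x) {
  if (x$kind == "predefined") {
    structure(list(kind = "predefined",
                   vocabulary = as.character(x$vocabulary),
                   term = as.character(x$term)), class = "dnf_choice")
  } else {
    structure(list(kind = "custom", text = trimws(as.character(x$text))),
              class = "dnf_choice")
  }
}

canon_choice_opt <- function(x) if (is.null(x)) NULL else canon_choice(x)

choice_sort_key <- function(x) {
  if (x$kind == "predefined") paste0("0\x01", x$term)
  else paste0("1\x01", trimws(x$text))
}

canon_choice_list <- function(xs) {
  xs <- lapply(xs, canon_choice)
  keys <- enc2utf8(vapply(xs, choice_sort_key, ""))
  xs[order(keys, method = "radix")]
}

canon_tool <- function(t) {
  structure(drop_null(list(
    tool = canon_choice(t$tool),
    database = if (!is.null(t$database)) as.character(t$database),
    evalue_threshold = if (!is.null(t$evalue_threshold))
      as.numeric(t$evalue_threshold),
    coverage_threshold = if (!is.null(t$coverage_threshold))
      as.numeric(t$coverage_threshold))), class = "dnf_tool")
}

tool_sort_key <- function(t) {
  paste(choice_sort_key(t$tool),
        t$database %||% "",
        if (is.null(t$evalue_threshold)) "" else num_to_str(t$evalue_threshold),
        if (is.null(t$coverage_threshold)) "" else num_to_str(t$coverage_threshold),
        sep = "\x01")
}

canon_searches <- function(xs) {
  xs <- lapply(xs, canon_tool)
  keys <- enc2utf8(vapply(xs, tool_sort_key, ""))
  xs[order(keys, method = "radix")]
}

canon_links <- function(xs) {
  xs <- lapply(xs, function(l) list(kind = as.character(l$kind),
                                    value = as.character(l$value)))
  keys <- enc2utf8(vapply(xs, function(l) paste(l$kind, l$value, sep = "\x01"), ""))
  xs[order(keys, method = "radix")]
}

# Structural equality on canonical forms.
ann_equal <- function(a, b) identical(canonicalize(a), canonicalize(b))
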