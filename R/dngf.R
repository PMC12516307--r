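#' Write an annotation as a .dngf document
#'
#' The dngf dialect is strict JSON with a fixed top-level key order
#' (`format_version`, then the six sections in document order), 2-space
#' indentation, UTF-8 encoding and a trailing newline. Absent optional
#' sections are omitted, never written as `null`. Writing always serializes
#' the canonical form, so the same methodology yields a byte-identical
#' document on every run and platform.
#'
#' @param ann A valid annotation.
#' @param path Optional output file path (conventionally with extension
#'   `.dngf`); when `NULL` the document text is returned.
#' @return The document as a single string (invisibly when `path` is given).
#' @seealso [read_dngf()]
#' @examples
#' ann <- denofo_annotation(
#'   dnf_input_data("ribosome_profiling"),
#'   dnf_evolutionary_information("phylostratigraphy"),
#'   dnf_homology_filter(dnf_tool("blast", evalue_threshold = 1e-5),
#'                       "no_hit_in_any_outgroup")
#' )
#' cat(write_dngf(ann))
#' @export
write_dngf <- function(ann, path = NULL) {
  ann <- canonicalize(ann)
  body <- list(format_version = ann$format_version)
  for (sec in dnf_sections()) {
    if (!is.null(ann[[sec]])) body[[sec]] <- section_to_json(sec, ann[[sec]])
  }
  text <- paste0(as.character(
    jsonlite::toJSON(body, auto_unbox = TRUE, pretty = 2, digits = NA,
                     null = "null")), "\n")
  if (!is.null(path)) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeBin(charToRaw(enc2utf8(text)), con)
    return(invisible(text))
  }
  text
}

#' Read a .dngf document
#'
#' Reading is lenient where writing is strict: unknown top-level keys are
#' ignored with a warning, and a predefined term that is not in this
#' build's vocabulary registry — as can happen when the document was written
#' under a newer minor format version — is preserved as a custom value
#' carrying the original term id, with a warning, never dropped.
#'
#' @param x A file path or the document text itself.
#' @return A validated, canonical `denofo_annotation`.
#' @section Errors:
#' Malformed JSON signals a `dngf_parse_error` with the offending line and
#' column; schema violations signal a `dnf_validation_error` listing every
#' violation; a document with an unsupported major `format_version` signals
#' a `dnf_version_error` naming both versions.
#' @seealso [write_dngf()]
#' @export
read_dngf <- function(x) {
  text <- if (length(x) == 1L && !grepl("[{\n]", x) && file.exists(x)) {
    readChar(x, file.size(x), useBytes = TRUE)
  } else paste(x, collapse = "\n")
  Encoding(text) <- "UTF-8"
  doc <- tryCatch(
    jsonlite::parse_json(text),
    error = function(e) {
      loc <- locate_parse_error(conditionMessage(e), text)
      stop_parse(sub("\\s+$", "", conditionMessage(e)), loc$line, loc$column)
    })
  if (!is.list(doc) || is.null(names(doc)))
    stop_parse("top level must be a JSON object")

  fv <- doc$format_version
  if (!is.null(fv))
    fv <- tryCatch(as.character(fv)[1], error = function(e) NULL)
  if (is.character(fv) && length(fv) == 1L && grepl("^[0-9]+\\.", fv) &&
      major_version(fv) != major_version(dnf_format_version())) {
    stop_version(sprintf(
      "document format_version '%s' is not supported by this build (supports '%s')",
      fv, dnf_format_version()), found = fv, supported = dnf_format_version())
  }
  known <- c("format_version", dnf_sections())
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("ignoring unknown top-level key(s): ", paste(extra, collapse = ", "),
            call. = FALSE)

  newer <- is.character(fv) && length(fv) == 1L &&
    grepl("^[0-9]+\\.[0-9]+$", fv) && fv != dnf_format_version()
  ann <- list(format_version = if (is.character(fv) && length(fv) == 1L) fv)
  for (sec in dnf_sections()) {
    ann[[sec]] <- if (!is.null(doc[[sec]]))
      section_from_json(sec, doc[[sec]], lenient_terms = newer)
  }
  res <- validate_annotation(ann)
  if (!res$valid) stop_validation(res$violations)
  canonicalize(ann)
}

# ---- model <-> JSON-shaped lists -------------------------------------------

choice_to_json <- function(x) {
  if (x$kind == "predefined")
    list(kind = "predefined", vocabulary = x$vocabulary, term = x$term)
  else list(kind = "custom", text = x$text)
}

tool_to_json <- function(t) {
  drop_null(list(tool = choice_to_json(t$tool),
                 database = t$database,
                 evalue_threshold = t$evalue_threshold,
                 coverage_threshold = t$coverage_threshold))
}

section_to_json <- function(sec, s) {
  switch(sec,
    input_data = drop_null(list(
      candidate_sources = lapply(s$candidate_sources, choice_to_json),
      orf_definition = if (!is.null(s$orf_definition))
        choice_to_json(s$orf_definition),
      minimum_orf_length_codons = s$minimum_orf_length_codons)),
    evolutionary_information = drop_null(list(
      age_inference = choice_to_json(s$age_inference),
      outgroup_count = s$outgroup_count,
      phylogeny_source = if (!is.null(s$phylogeny_source))
        choice_to_json(s$phylogeny_source))),
    homology_filter = list(
      searches = lapply(s$searches, tool_to_json),
      homology_criterion = choice_to_json(s$homology_criterion)),
    non_coding_homologs = list(
      required_for_classification = s$required_for_classification,
      detection_methods = lapply(s$detection_methods, choice_to_json)),
    lab_verification = list(
      transcription_evidence = lapply(s$transcription_evidence, choice_to_json),
      translation_evidence = lapply(s$translation_evidence, choice_to_json)),
    hyperlinks = list(links = lapply(s$links, function(l)
      list(kind = l$kind, value = l$value)))
  )
}

scalar_chr <- function(x) if (is.null(x)) NULL else as.character(x)

choice_from_json <- function(x, vocabulary, lenient_terms = FALSE) {
  if (!is.list(x) || is.null(x$kind)) return(x)
  if (identical(x$kind, "predefined")) {
    voc <- scalar_chr(x$vocabulary) %||% vocabulary
    term <- scalar_chr(x$term) %||% ""
    if (lenient_terms && !vocab_has(voc, term)) {
      warning(sprintf(
        "unknown term '%s' in vocabulary '%s' (newer format version); preserved as a custom value",
        term, voc), call. = FALSE)
      return(dnf_custom(term))
    }
    dnf_predefined(voc, term)
  } else if (identical(x$kind, "custom")) {
    dnf_custom(scalar_chr(x$text) %||% "")
  } else x
}

choices_from_json <- function(xs, vocabulary, lenient_terms) {
  if (!is.list(xs)) return(xs)
  lapply(xs, choice_from_json, vocabulary = vocabulary,
         lenient_terms = lenient_terms)
}

tool_from_json <- function(t, lenient_terms) {
  if (!is.list(t)) return(t)
  list(tool = choice_from_json(t$tool %||% list(), "homology_tools",
                               lenient_terms),
       database = scalar_chr(t$database),
       evalue_threshold = if (!is.null(t$evalue_threshold))
         as.numeric(t$evalue_threshold),
       coverage_threshold = if (!is.null(t$coverage_threshold))
         as.numeric(t$coverage_threshold))
}

section_from_json <- function(sec, s, lenient_terms = FALSE) {
  if (!is.list(s)) return(s)
  switch(sec,
    input_data = list(
      candidate_sources = choices_from_json(s$candidate_sources %||% list(),
                                            "candidate_sources", lenient_terms),
      orf_definition = if (!is.null(s$orf_definition))
        choice_from_json(s$orf_definition, "orf_definition", lenient_terms),
      minimum_orf_length_codons = if (!is.null(s$minimum_orf_length_codons))
        as.numeric(s$minimum_orf_length_codons)),
    evolutionary_information = list(
      age_inference = if (!is.null(s$age_inference))
        choice_from_json(s$age_inference, "age_inference", lenient_terms),
      outgroup_count = if (!is.null(s$outgroup_count))
        as.numeric(s$outgroup_count),
      phylogeny_source = if (!is.null(s$phylogeny_source))
        choice_from_json(s$phylogeny_source, "phylogeny_source", lenient_terms)),
    homology_filter = list(
      searches = if (is.list(s$searches))
        lapply(s$searches, tool_from_json, lenient_terms = lenient_terms)
        else s$searches,
      homology_criterion = if (!is.null(s$homology_criterion))
        choice_from_json(s$homology_criterion, "homology_criterion",
                         lenient_terms)),
    non_coding_homologs = list(
      required_for_classification =
        if (is.logical(s$required_for_classification %||% NA))
          s$required_for_classification else s$required_for_classification,
      detection_methods = choices_from_json(s$detection_methods %||% list(),
                                            "noncoding_detection",
                                            lenient_terms)),
    lab_verification = list(
      transcription_evidence =
        choices_from_json(s$transcription_evidence %||% list(),
                          "transcription_evidence", lenient_terms),
      translation_evidence =
        choices_from_json(s$translation_evidence %||% list(),
                          "translation_evidence", lenient_terms)),
    hyperlinks = list(links = if (is.list(s$links))
      lapply(s$links, function(l)
        if (is.list(l)) list(kind = scalar_chr(l$kind),
                             value = scalar_chr(l$value)) else l)
      else s$links)
  )
}

# yajl reports no byte offset; recover an approximate line/column by
# locating its context snippet (the text just before the caret, with
# newlines flattened to spaces) back in the document.
locate_parse_error <- function(msg, text) {
  lines <- strsplit(msg, "\n", fixed = TRUE)[[1]]
  caret <- grep("\\(right here\\)", lines)
  if (length(caret) != 1L || caret < 2L)
    return(list(line = NA_integer_, column = NA_integer_))
  context <- sub("^\\s+", "", lines[[caret - 1L]])
  if (!nzchar(context)) return(list(line = NA_integer_, column = NA_integer_))
  toks <- strsplit(context, "[ \t]+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0L) return(list(line = NA_integer_, column = NA_integer_))
  rx <- paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", toks),
              collapse = "[ \t\n]+")
  pos <- regexpr(rx, text, useBytes = TRUE)
  if (pos < 0) return(list(line = NA_integer_, column = NA_integer_))
  end <- as.integer(pos) + attr(pos, "match.length") - 1L
  before <- substr(text, 1L, end)
  nl <- gregexpr("\n", before, fixed = TRUE)[[1]]
  nl <- nl[nl > 0]
  list(line = length(nl) + 1L,
       column = end - (if (length(nl)) max(nl) else 0L))
}
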