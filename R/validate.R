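#' Validate an annotation against the DeNoFo schema
#'
#' Checks a (possibly hand-built) annotation-shaped list against every rule
#' of the format: presence of the three required sections, controlled
#' vocabulary membership, threshold ranges, the non-coding homolog
#' consistency rule, the `none` exclusivity rule for evidence lists, and
#' link syntax. All problems are reported together; nothing is thrown.
#'
#' @param ann A `denofo_annotation` or any list with addressable fields of
#'   the same shape.
#' @return A `dnf_validation` object: `list(valid, violations)` where
#'   `violations` is a data frame with columns `path` and `message`;
#'   `valid` is `TRUE` iff `violations` has zero rows.
#' @examples
#' good <- denofo_annotation(
#'   dnf_input_data("genome_annotation"),
#'   dnf_evolutionary_information("synteny_based"),
#'   dnf_homology_filter(dnf_tool("blast"), "no_hit_in_any_outgroup")
#' )
#' validate_annotation(good)$valid
#'
#' bad <- unclass(good)
#' bad$homology_filter <- NULL
#' validate_annotation(bad)
#' @export
validate_annotation <- function(ann) {
  v <- new_collector()
  if (!is.list(ann)) {
    v$add("", "annotation must be a list with named fields")
    return(validation_result(v))
  }
  fv <- ann$format_version
  if (is.null(fv) || !is.character(fv) || length(fv) != 1L ||
      !grepl("^[0-9]+\\.[0-9]+$", fv)) {
    v$add("format_version", "missing or malformed version string (expected e.g. \"1.0\")")
    fv <- dnf_format_version()
  }
  for (sec in REQUIRED_SECTIONS) {
    if (is.null(ann[[sec]])) v$add(sec, "required section missing")
  }
  if (!is.null(ann$input_data)) check_input_data(ann$input_data, v)
  if (!is.null(ann$evolutionary_information))
    check_evo_info(ann$evolutionary_information, v)
  if (!is.null(ann$homology_filter)) check_homology_filter(ann$homology_filter, v)
  if (!is.null(ann$non_coding_homologs))
    check_non_coding_homologs(ann$non_coding_homologs, v)
  if (!is.null(ann$lab_verification)) check_lab_verification(ann$lab_verification, v)
  if (!is.null(ann$hyperlinks)) check_hyperlinks(ann$hyperlinks, v)
  validation_result(v)
}

#' @export
print.dnf_validation <- function(x, ...) {
  if (x$valid) {
    cat("valid DeNoFo annotation (0 violations)\n")
  } else {
    cat("INVALID DeNoFo annotation:", nrow(x$violations), "violation(s)\n")
    for (i in seq_len(nrow(x$violations)))
      cat("  -", x$violations$path[i], ":", x$violations$message[i], "\n")
  }
  invisible(x)
}

new_collector <- function() {
  paths <- character(0); msgs <- character(0)
  list(
    add = function(path, message) {
      paths <<- c(paths, path); msgs <<- c(msgs, message)
    },
    rows = function() data.frame(path = paths, message = msgs,
                                 stringsAsFactors = FALSE)
  )
}

validation_result <- function(v) {
  rows <- v$rows()
  structure(list(valid = nrow(rows) == 0L, violations = rows),
            class = "dnf_validation")
}

check_choice <- function(x, path, vocabulary, v) {
  if (!is_choice(x)) {
    v$add(path, "not a choice value (expected kind predefined or custom)")
    return(invisible(FALSE))
  }
  if (x$kind == "predefined") {
    if (is.null(x$vocabulary) || is.null(x$term)) {
      v$add(path, "predefined choice lacks vocabulary/term")
    } else if (x$vocabulary != vocabulary) {
      v$add(path, sprintf("wrong vocabulary '%s' (expected '%s')",
                          x$vocabulary, vocabulary))
    } else if (!vocab_has(vocabulary, x$term)) {
      v$add(path, sprintf("unknown term '%s' in vocabulary '%s'",
                          x$term, vocabulary))
    }
  } else {
    if (is.null(x$text) || !is.character(x$text) || length(x$text) != 1L ||
        !nzchar(trimws(x$text))) {
      v$add(path, "custom answer text must be non-empty after trimming")
    }
  }
  invisible(TRUE)
}

check_choice_list <- function(xs, path, vocabulary, v, min_len = 0L,
                              none_exclusive = FALSE) {
  if (!is.list(xs) || !is.null(xs$kind)) {
    v$add(path, "expected a list of choice values")
    return(invisible(NULL))
  }
  if (length(xs) < min_len)
    v$add(path, sprintf("at least %d entr%s required", min_len,
                        if (min_len == 1L) "y is" else "ies are"))
  for (i in seq_along(xs))
    check_choice(xs[[i]], sprintf("%s[%d]", path, i), vocabulary, v)
  terms <- vapply(xs, function(x)
    if (is_choice(x) && x$kind == "predefined" && !is.null(x$term)) x$term
    else NA_character_, "")
  dup <- unique(terms[!is.na(terms) & duplicated(terms)])
  if (length(dup))
    v$add(path, paste0("duplicate predefined term(s): ",
                       paste(dup, collapse = ", ")))
  if (none_exclusive && "none" %in% terms && length(xs) > 1L)
    v$add(path, "'none' may not co-occur with other evidence terms")
  invisible(NULL)
}

check_count <- function(x, path, v, min = 0) {
  if (is.null(x)) return(invisible(NULL))
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min)
    v$add(path, sprintf("must be an integer >= %d", min))
  invisible(NULL)
}

check_input_data <- function(s, v) {
  check_choice_list(s$candidate_sources, "input_data.candidate_sources",
                    "candidate_sources", v, min_len = 1L)
  if (!is.null(s$orf_definition))
    check_choice(s$orf_definition, "input_data.orf_definition",
                 "orf_definition", v)
  check_count(s$minimum_orf_length_codons,
              "input_data.minimum_orf_length_codons", v, min = 1)
}

check_evo_info <- function(s, v) {
  if (is.null(s$age_inference)) {
    v$add("evolutionary_information.age_inference", "required field missing")
  } else {
    check_choice(s$age_inference, "evolutionary_information.age_inference",
                 "age_inference", v)
  }
  check_count(s$outgroup_count, "evolutionary_information.outgroup_count", v,
              min = 0)
  if (!is.null(s$phylogeny_source))
    check_choice(s$phylogeny_source, "evolutionary_information.phylogeny_source",
                 "phylogeny_source", v)
}

check_tool <- function(t, path, v) {
  if (!is.list(t) || is.null(t$tool)) {
    v$add(path, "not a tool invocation (missing tool)")
    return(invisible(NULL))
  }
  check_choice(t$tool, paste0(path, ".tool"), "homology_tools", v)
  if (!is.null(t$database) &&
      (!is.character(t$database) || length(t$database) != 1L))
    v$add(paste0(path, ".database"), "database must be a single string")
  if (!is.null(t$evalue_threshold) &&
      (!is.numeric(t$evalue_threshold) || length(t$evalue_threshold) != 1L ||
       is.na(t$evalue_threshold) || t$evalue_threshold <= 0))
    v$add(paste0(path, ".evalue_threshold"), "must be a positive number")
  if (!is.null(t$coverage_threshold) &&
      (!is.numeric(t$coverage_threshold) || length(t$coverage_threshold) != 1L ||
       is.na(t$coverage_threshold) || t$coverage_threshold < 0 ||
       t$coverage_threshold > 1))
    v$add(paste0(path, ".coverage_threshold"), "must lie in [0, 1]")
  invisible(NULL)
}

check_homology_filter <- function(s, v) {
  if (!is.list(s$searches) || length(s$searches) < 1L) {
    v$add("homology_filter.searches", "at least one search is required")
  } else {
    for (i in seq_along(s$searches))
      check_tool(s$searches[[i]], sprintf("homology_filter.searches[%d]", i), v)
  }
  if (is.null(s$homology_criterion)) {
    v$add("homology_filter.homology_criterion", "required field missing")
  } else {
    check_choice(s$homology_criterion, "homology_filter.homology_criterion",
                 "homology_criterion", v)
  }
}

check_non_coding_homologs <- function(s, v) {
  if (!is.logical(s$required_for_classification) ||
      length(s$required_for_classification) != 1L ||
      is.na(s$required_for_classification)) {
    v$add("non_coding_homologs.required_for_classification",
          "must be TRUE or FALSE")
  } else if (isTRUE(s$required_for_classification) &&
             length(s$detection_methods) == 0L) {
    v$add("non_coding_homologs.detection_methods",
          "at least one detection method is required when non-coding homologs are required for classification")
  }
  check_choice_list(s$detection_methods %||% list(),
                    "non_coding_homologs.detection_methods",
                    "noncoding_detection", v)
}

check_lab_verification <- function(s, v) {
  check_choice_list(s$transcription_evidence %||% list(),
                    "lab_verification.transcription_evidence",
                    "transcription_evidence", v, none_exclusive = TRUE)
  check_choice_list(s$translation_evidence %||% list(),
                    "lab_verification.translation_evidence",
                    "translation_evidence", v, none_exclusive = TRUE)
}

check_hyperlinks <- function(s, v) {
  if (!is.list(s$links)) {
    v$add("hyperlinks.links", "expected a list of links")
    return(invisible(NULL))
  }
  for (i in seq_along(s$links)) {
    l <- s$links[[i]]
    path <- sprintf("hyperlinks.links[%d]", i)
    if (!is.list(l) || is.null(l$kind) || is.null(l$value)) {
      v$add(path, "link needs kind and value")
    } else if (!l$kind %in% c("url", "doi")) {
      v$add(path, sprintf("unknown link kind '%s'", l$kind))
    } else if (l$kind == "doi" && !grepl("^10\\.[0-9]+/.+", l$value)) {
      v$add(path, "DOI must match 10.<digits>/<suffix>")
    } else if (l$kind == "url" &&
               !grepl("^[A-Za-z][A-Za-z0-9+.-]*://", l$value)) {
      v$add(path, "URL must start with a scheme followed by ://")
    }
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
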