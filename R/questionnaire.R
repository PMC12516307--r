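# UI-independent questionnaire engine. The state machine is pure
# (state in, state out, no terminal I/O), so the CLI readline loop — or any
# future GUI — is a thin driver over answer_current()/go_back()/finalize().

question <- function(id, target_path, prompt, answer_kind,
                     vocabulary = NULL, required = TRUE, gate = FALSE,
                     applicable_when = NULL, min = NULL) {
  list(id = id, target_path = target_path, prompt = prompt,
       answer_kind = answer_kind, vocabulary = vocabulary,
       options = if (!is.null(vocabulary)) dnf_vocabularies()[[vocabulary]],
       required = required, gate = gate,
       applicable_when = applicable_when, min = min)
}

#' Build the interactive questionnaire
#'
#' Returns the ordered, branching question sequence that walks a user
#' through every field of the format, section by section. Each optional
#' section opens with a yes/no gate question; declining it skips the
#' section's questions. Choice questions offer the controlled vocabulary
#' as pre-populated options plus a custom free-text escape.
#'
#' @param format_version Format version to build questions for.
#' @return A `dnf_questionnaire` state with the cursor at the first
#'   question and no answers.
#' @examples
#' st <- build_questionnaire()
#' current_question(st)$target_path
#' @export
build_questionnaire <- function(format_version = dnf_format_version()) {
  check_format_version(format_version)
  qs <- list(
    question("candidate_sources", "input_data.candidate_sources",
             "Where did your candidate de novo genes/ORFs come from? (select all that apply)",
             "multi_choice", "candidate_sources"),
    question("orf_definition", "input_data.orf_definition",
             "How were ORFs defined?", "single_choice", "orf_definition",
             required = FALSE),
    question("minimum_orf_length", "input_data.minimum_orf_length_codons",
             "Minimum ORF length in codons (leave blank if none)?",
             "integer", required = FALSE, min = 1),
    question("age_inference", "evolutionary_information.age_inference",
             "How was gene age / lineage specificity inferred?",
             "single_choice", "age_inference"),
    question("outgroup_count", "evolutionary_information.outgroup_count",
             "How many outgroup species were examined (leave blank if not applicable)?",
             "integer", required = FALSE, min = 0),
    question("phylogeny_source", "evolutionary_information.phylogeny_source",
             "Where did the species phylogeny come from?",
             "single_choice", "phylogeny_source", required = FALSE),
    question("searches", "homology_filter.searches",
             "Which homology search tools established the absence of homologs? (select all that apply)",
             "multi_choice", "homology_tools"),
    question("homology_criterion", "homology_filter.homology_criterion",
             "What counted as absence of homology?",
             "single_choice", "homology_criterion"),
    question("include_non_coding_homologs", "non_coding_homologs",
             "Did your study assess non-coding homologous regions in outgroups?",
             "boolean", gate = TRUE),
    question("required_for_classification",
             "non_coding_homologs.required_for_classification",
             "Was a detectable non-coding homolog required to classify a gene as de novo?",
             "boolean",
             applicable_when = function(ans)
               isTRUE(ans$include_non_coding_homologs)),
    question("detection_methods", "non_coding_homologs.detection_methods",
             "How were non-coding homologous regions detected? (select all that apply)",
             "multi_choice", "noncoding_detection",
             applicable_when = function(ans)
               isTRUE(ans$include_non_coding_homologs) &&
               isTRUE(ans$required_for_classification)),
    question("include_lab_verification", "lab_verification",
             "Does your study include transcription/translation verification?",
             "boolean", gate = TRUE),
    question("transcription_evidence",
             "lab_verification.transcription_evidence",
             "What transcription evidence was collected? ('none' excludes other answers)",
             "multi_choice", "transcription_evidence",
             applicable_when = function(ans)
               isTRUE(ans$include_lab_verification)),
    question("translation_evidence", "lab_verification.translation_evidence",
             "What translation evidence was collected? ('none' excludes other answers)",
             "multi_choice", "translation_evidence",
             applicable_when = function(ans)
               isTRUE(ans$include_lab_verification)),
    question("include_hyperlinks", "hyperlinks",
             "Do you want to attach hyperlinks (URLs/DOIs)?",
             "boolean", gate = TRUE),
    question("links", "hyperlinks.links",
             "Enter links, whitespace-separated (DOIs as 10.<digits>/<suffix>, URLs with scheme).",
             "text",
             applicable_when = function(ans) isTRUE(ans$include_hyperlinks))
  )
  st <- structure(list(questions = qs, cursor = 1L,
                       answers = list(),
                       format_version = format_version),
                  class = "dnf_questionnaire")
  st$cursor <- next_applicable(st, 0L)
  st
}

question_index <- function(st, id) {
  match(id, vapply(st$questions, `[[`, "", "id"))
}

is_applicable <- function(st, i) {
  q <- st$questions[[i]]
  is.null(q$applicable_when) || isTRUE(q$applicable_when(st$answers))
}

next_applicable <- function(st, from) {
  i <- from + 1L
  while (i <= length(st$questions) && !is_applicable(st, i)) i <- i + 1L
  i
}

prev_applicable <- function(st, from) {
  i <- from - 1L
  while (i >= 1L && !is_applicable(st, i)) i <- i - 1L
  i
}

#' Inspect the questionnaire cursor
#'
#' @param st A `dnf_questionnaire` state.
#' @return The current question (a list with `id`, `prompt`, `answer_kind`,
#'   `options`, ...), or `NULL` when the questionnaire is complete.
#' @export
current_question <- function(st) {
  if (st$cursor > length(st$questions)) NULL else st$questions[[st$cursor]]
}

coerce_answer <- function(q, value) {
  err <- function(msg) stop(dnf_error(
    sprintf("question '%s': %s", q$id, msg), "dnf_input_error"))
  switch(q$answer_kind,
    boolean = {
      if (!is.logical(value) || length(value) != 1L || is.na(value))
        err("expected TRUE or FALSE")
      value
    },
    integer = {
      if (is.null(value)) return(NULL)  # optional numeric: blank = skip
      if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
          value != floor(value))
        err("expected a whole number")
      if (!is.null(q$min) && value < q$min)
        err(sprintf("expected a value >= %d", q$min))
      as.integer(value)
    },
    real = {
      if (is.null(value)) return(NULL)
      if (!is.numeric(value) || length(value) != 1L || is.na(value))
        err("expected a number")
      as.numeric(value)
    },
    text = {
      if (!is.character(value) || length(value) != 1L)
        err("expected text")
      value
    },
    single_choice = {
      if (is.null(value) && !q$required) return(NULL)
      ch <- to_choice(q, value, err)
      ch
    },
    multi_choice = {
      if (is.null(value)) value <- list()
      if (is.character(value)) value <- as.list(value)
      if (is_choice(value)) value <- list(value)
      if (!is.list(value)) err("expected one or more choices")
      lapply(value, function(v) to_choice(q, v, err))
    })
}

to_choice <- function(q, value, err) {
  if (is_choice(value)) return(value)
  if (!is.character(value) || length(value) != 1L)
    err("expected a vocabulary term or custom text")
  if (value %in% q$options) dnf_predefined(q$vocabulary, value)
  else if (nzchar(trimws(value))) dnf_custom(value)
  else err("empty answer")
}

#' Answer the current question
#'
#' Records `value` for the question under the cursor and advances to the
#' next applicable question. Choice questions accept a vocabulary term,
#' arbitrary custom text, or `dnf_choice` values; optional integer/choice
#' questions accept `NULL` meaning "skip". Answers to questions that become
#' inapplicable (because a gate was changed) are discarded.
#'
#' @param st A `dnf_questionnaire` state.
#' @param value The answer.
#' @return The updated state.
#' @export
answer_current <- function(st, value) {
  q <- current_question(st)
  if (is.null(q))
    stop(dnf_error("questionnaire is complete; no current question",
                   "dnf_navigation_error"))
  ans <- coerce_answer(q, value)
  if (is.null(ans)) st$answers[q$id] <- list(NULL)
  else st$answers[[q$id]] <- ans
  # Drop answers invalidated by branching, then advance.
  for (i in seq_along(st$questions)) {
    id <- st$questions[[i]]$id
    if (!is_applicable(st, i) && id %in% names(st$answers))
      st$answers[[id]] <- NULL
  }
  st$cursor <- next_applicable(st, st$cursor)
  st
}

#' Move back to the previous applicable question
#'
#' Existing answers are retained until overwritten.
#'
#' @param st A `dnf_questionnaire` state.
#' @return The updated state; signals a `dnf_navigation_error` (state
#'   unchanged) when already at the first question.
#' @export
go_back <- function(st) {
  prev <- prev_applicable(st, st$cursor)
  if (prev < 1L)
    stop(dnf_error("already at the first question", "dnf_navigation_error"))
  st$cursor <- prev
  st
}

#' Assemble the annotation from questionnaire answers
#'
#' @param st A `dnf_questionnaire` state.
#' @return A valid canonical `denofo_annotation`. If any applicable
#'   required question is unanswered, a `dnf_completeness_error` is
#'   signalled listing every missing question by prompt.
#' @export
finalize <- function(st) {
  ans <- st$answers
  missing <- character(0)
  for (i in seq_along(st$questions)) {
    q <- st$questions[[i]]
    if (q$required && is_applicable(st, i) && is.null(ans[[q$id]]))
      missing <- c(missing, q$prompt)
  }
  if (length(missing))
    stop(dnf_error(paste0("questionnaire incomplete; unanswered:\n",
                          paste0("  - ", missing, collapse = "\n")),
                   "dnf_completeness_error", missing = missing))

  input_data <- list(
    candidate_sources = ans$candidate_sources,
    orf_definition = ans$orf_definition,
    minimum_orf_length_codons = ans$minimum_orf_length)
  evo <- list(
    age_inference = ans$age_inference,
    outgroup_count = ans$outgroup_count,
    phylogeny_source = ans$phylogeny_source)
  hf <- list(
    searches = lapply(ans$searches, function(ch) dnf_tool(ch)),
    homology_criterion = ans$homology_criterion)
  ncs <- if (isTRUE(ans$include_non_coding_homologs)) {
    list(required_for_classification = ans$required_for_classification,
         detection_methods = ans$detection_methods %||% list())
  }
  lab <- if (isTRUE(ans$include_lab_verification)) {
    list(transcription_evidence = ans$transcription_evidence,
         translation_evidence = ans$translation_evidence)
  }
  links <- if (isTRUE(ans$include_hyperlinks)) {
    dnf_hyperlinks(strsplit(trimws(ans$links), "[ \t\n]+")[[1]])
  }
  canonicalize(denofo_annotation(
    input_data, evo, hf, non_coding_homologs = ncs, lab_verification = lab,
    hyperlinks = links, format_version = st$format_version))
}

#' @export
print.dnf_questionnaire <- function(x, ...) {
  q <- current_question(x)
  cat("<dnf_questionnaire>", length(x$answers), "answer(s);")
  if (is.null(q)) cat(" complete\n")
  else cat(" current:", q$id, "\n")
  invisible(x)
}
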