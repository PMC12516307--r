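#' Controlled vocabulary registry
#'
#' The DeNoFo format fixes, per format version, a set of controlled
#' vocabularies (candidate sources, age-inference approaches, homology
#' tools, evidence types, ...). Term order within each vocabulary is frozen
#' for a given format version because the shortcode serializes predefined
#' terms as indices into that order. The registry ships as a JSON data file
#' so that terms can be added in later format versions without code changes.
#'
#' @param format_version Format version string, e.g. `"1.0"`.
#' @return A named list mapping vocabulary id to an ordered character vector
#'   of term ids.
#' @examples
#' names(dnf_vocabularies())
#' dnf_vocabularies()$age_inference
#' @export
dnf_vocabularies <- function(format_version = dnf_format_version()) {
  check_format_version(format_version)
  key <- paste0("vocabularies-", major_version(format_version))
  cached <- vocab_cache[[key]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata",
                      sprintf("vocabularies-%s.0.json", major_version(format_version)),
                      package = "denofor", mustWork = TRUE)
  reg <- jsonlite::parse_json(readChar(path, file.size(path), useBytes = TRUE))
  voc <- lapply(reg$vocabularies, function(v) vapply(v, identical_chr, ""))
  vocab_cache[[key]] <- voc
  voc
}

identical_chr <- function(x) as.character(x)

vocab_cache <- new.env(parent = emptyenv())

#' Current DeNoFo format version
#'
#' @return The format version string this package writes by default.
#' @export
dnf_format_version <- function() "1.0"

# Major version component of "X.Y" as a string.
major_version <- function(v) sub("\\..*$", "", v)

check_format_version <- function(v) {
  if (!is.character(v) || length(v) != 1L || !grepl("^[0-9]+\\.[0-9]+$", v)) {
    stop_version(sprintf("malformed format_version %s", deparse(v)), found = v)
  }
  if (major_version(v) != "1") {
    stop_version(sprintf(
      "unsupported format_version '%s' (this build supports major version 1, e.g. '%s')",
      v, dnf_format_version()), found = v, supported = dnf_format_version())
  }
  invisible(v)
}

# TRUE iff term is a member of the named vocabulary.
vocab_has <- function(vocabulary, term, format_version = dnf_format_version()) {
  voc <- dnf_vocabularies(format_version)
  !is.null(voc[[vocabulary]]) && term %in% voc[[vocabulary]]
}

# 0-based frozen index of a term; used by the shortcode codec.
vocab_index <- function(vocabulary, term, format_version = dnf_format_version()) {
  voc <- dnf_vocabularies(format_version)[[vocabulary]]
  match(term, voc) - 1L
}

vocab_term_at <- function(vocabulary, index, format_version = dnf_format_version()) {
  voc <- dnf_vocabularies(format_version)[[vocabulary]]
  if (is.na(index) || index < 0L || index >= length(voc)) return(NA_character_)
  voc[[index + 1L]]
}
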