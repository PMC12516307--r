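#' Compare the methodology of two studies
#'
#' Produces a field-by-field report over the schema's leaf fields. Both
#' annotations are canonicalized first, so ordering and whitespace never
#' masquerade as methodological differences; list-valued fields compare as
#' sets of canonical values. A custom answer never equals a predefined term,
#' even when the text coincides — free text and controlled terms are
#' different claims. Leaves of an optional section present in only one
#' study are reported as `only_in_first`/`only_in_second`.
#'
#' @param a,b Valid annotations (from [read_dngf()], [extract_fasta()],
#'   [decode_shortcode()], ...).
#' @return A `dnf_comparison` with one entry per schema leaf
#'   (`path`, `status`, `value_first`, `value_second`) plus the four status
#'   counts, and a version-mismatch flag when the two annotations carry
#'   different major format versions.
#' @seealso [render_report()]
#' @examples
#' a <- generate_annotation(fixture_config(seed = 7, p_optional = 1))
#' rep <- compare_annotations(a, a)
#' rep$n_differs
#' @export
compare_annotations <- function(a, b) {
  a <- canonicalize(a)
  b <- canonicalize(b)
  leaves <- schema_leaves()
  entries <- lapply(seq_len(nrow(leaves)), function(i) {
    leaf_entry(leaves$path[i], leaves$kind[i], a, b)
  })
  entries <- do.call(rbind, entries)
  counts <- table(factor(entries$status,
                         levels = c("equal", "differs",
                                    "only_in_first", "only_in_second")))
  structure(list(
    entries = entries,
    n_equal = as.integer(counts[["equal"]]),
    n_differs = as.integer(counts[["differs"]]),
    n_only_first = as.integer(counts[["only_in_first"]]),
    n_only_second = as.integer(counts[["only_in_second"]]),
    format_version_first = a$format_version,
    format_version_second = b$format_version,
    version_mismatch =
      major_version(a$format_version) != major_version(b$format_version)),
    class = "dnf_comparison")
}

leaf_value <- function(ann, path) {
  sec <- ann[[leaf_section(path)]]
  if (is.null(sec)) return(NULL)
  sec[[leaf_field(path)]]
}

# Stable, set-semantic rendering of a leaf value.
render_leaf <- function(value, kind) {
  if (is.null(value)) return(NULL)
  switch(kind,
    choice = render_choice(value),
    choice_list = paste(vapply(value, render_choice, ""), collapse = " | "),
    tool_list = paste(vapply(value, render_tool, ""), collapse = " | "),
    link_list = paste(vapply(value, render_link, ""), collapse = " | "),
    integer = as.character(value),
    boolean = if (isTRUE(value)) "yes" else "no")
}

leaf_entry <- function(path, kind, a, b) {
  sec <- leaf_section(path)
  in_a <- !is.null(a[[sec]])
  in_b <- !is.null(b[[sec]])
  va <- if (in_a) leaf_value(a, path)
  vb <- if (in_b) leaf_value(b, path)
  ra <- render_leaf(va, kind)
  rb <- render_leaf(vb, kind)
  status <- if (in_a && !in_b) "only_in_first"
    else if (!in_a && in_b) "only_in_second"
    else if (is.null(ra) && !is.null(rb)) "only_in_second"
    else if (!is.null(ra) && is.null(rb)) "only_in_first"
    else if (identical(ra, rb)) "equal"
    else "differs"
  data.frame(path = path, status = status,
             value_first = ra %||% "(absent)",
             value_second = rb %||% "(absent)",
             stringsAsFactors = FALSE)
}

#' Render a comparison report
#'
#' @param rep A `dnf_comparison`.
#' @param mode `"differences"` lists only non-equal entries,
#'   `"similarities"` only equal ones; the two modes partition the report.
#'   Both end with the four status counts.
#' @return The report as a single UTF-8 string, stable across runs.
#' @export
render_report <- function(rep, mode = c("differences", "similarities")) {
  mode <- match.arg(mode)
  e <- rep$entries
  keep <- if (mode == "differences") e$status != "equal" else e$status == "equal"
  body <- e[keep, , drop = FALSE]
  out <- c(sprintf("DeNoFo comparison report (%s)", mode),
           sprintf("format versions: %s vs %s%s",
                   rep$format_version_first, rep$format_version_second,
                   if (rep$version_mismatch)
                     "  ** WARNING: major format version mismatch **" else ""),
           "")
  if (nrow(body) == 0L) {
    out <- c(out, if (mode == "differences")
      "The two studies report no methodological differences."
      else "The two studies share no identically annotated fields.")
  } else {
    for (sec in unique(leaf_section(body$path))) {
      rows <- body[leaf_section(body$path) == sec, , drop = FALSE]
      out <- c(out, paste0("[", sec, "]"))
      for (i in seq_len(nrow(rows))) {
        field <- leaf_field(rows$path[i])
        out <- c(out, switch(rows$status[i],
          equal = sprintf("  %s: %s", field, rows$value_first[i]),
          differs = sprintf("  %s: %s  <>  %s", field,
                            rows$value_first[i], rows$value_second[i]),
          only_in_first = sprintf("  %s: %s  (only in first)", field,
                                  rows$value_first[i]),
          only_in_second = sprintf("  %s: %s  (only in second)", field,
                                   rows$value_second[i])))
      }
      out <- c(out, "")
    }
  }
  out <- c(out, sprintf(
    "counts: equal=%d differing=%d only_in_first=%d only_in_second=%d",
    rep$n_equal, rep$n_differs, rep$n_only_first, rep$n_only_second))
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @export
print.dnf_comparison <- function(x, ...) {
  cat(render_report(x, "differences"))
  invisible(x)
}
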