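#' Record selections for carrier annotation
#'
#' Annotation and extraction can target all records of a carrier file, an
#' explicit id set, or every id matching a regular expression. FASTA
#' records are identified by the first word of their header; GFF3 features
#' by their `ID` attribute, falling back to `<seqid>:<start>-<end>`.
#'
#' @param ids Character vector of record/feature identifiers.
#' @param pattern Regular expression matched against identifiers.
#' @return A `dnf_selection`.
#' @export
select_all <- function() {
  structure(list(mode = "all"), class = "dnf_selection")
}

#' @rdname select_all
#' @export
select_ids <- function(ids) {
  structure(list(mode = "ids", ids = as.character(ids)),
            class = "dnf_selection")
}

#' @rdname select_all
#' @export
select_pattern <- function(pattern) {
  structure(list(mode = "pattern", pattern = pattern),
            class = "dnf_selection")
}

selected <- function(sel, id) {
  switch(sel$mode,
         all = TRUE,
         ids = id %in% sel$ids,
         pattern = grepl(sel$pattern, id))
}

warn_unmatched <- function(sel, seen) {
  if (sel$mode == "ids") {
    missing <- setdiff(sel$ids, seen)
    if (length(missing))
      warning("selection id(s) not found in carrier: ",
              paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(NULL)
}

TOKEN_RX <- "DNF[0-9]:[A-Za-z0-9._-]+"

# Carrier text handling: one code path over the full text, so that output
# is byte-identical to input everywhere a token was not inserted.
carrier_text <- function(x) {
  text <- if (length(x) == 1L && !grepl("[\n>#\t]", x) && file.exists(x)) {
    readChar(x, file.size(x), useBytes = TRUE)
  } else paste(x, collapse = "\n")
  Encoding(text) <- "UTF-8"
  text
}

split_keep_trailing <- function(text) {
  trailing <- grepl("\n$", text)
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(lines) == 0L) lines <- ""
  list(lines = lines, trailing = trailing)
}

join_lines <- function(parts) {
  paste0(paste(parts$lines, collapse = "\n"), if (parts$trailing) "\n")
}

write_text <- function(text, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(enc2utf8(text)), con)
  invisible(text)
}

fasta_id <- function(header) {
  strsplit(sub("^>", "", header), "[ \t]")[[1]][1]
}

#' Embed an annotation in FASTA headers
#'
#' Appends ` denofo=<shortcode>` as the last word of each selected record's
#' header line. Sequence lines and unselected records are untouched
#' byte-for-byte; a record that already carries a denofo token has it
#' replaced, never duplicated.
#'
#' @param input FASTA file path or FASTA text.
#' @param ann A valid annotation.
#' @param sel A selection from [select_all()], [select_ids()] or
#'   [select_pattern()].
#' @param path Optional output path.
#' @return The annotated FASTA text (invisibly when `path` is given).
#' @seealso [extract_fasta()]
#' @export
annotate_fasta <- function(input, ann, sel = select_all(), path = NULL) {
  token <- encode_shortcode(ann)
  parts <- split_keep_trailing(carrier_text(input))
  lines <- parts$lines
  headers <- startsWith(lines, ">")
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L || !startsWith(lines[nonblank[1]], ">"))
    stop_parse("not a FASTA stream: first record has no '>' header")
  seen <- character(0)
  for (i in which(headers)) {
    id <- fasta_id(lines[i])
    if (is.na(id) || !nzchar(id))
      stop_parse(sprintf("FASTA record at line %d has an empty identifier", i))
    seen <- c(seen, id)
    if (selected(sel, id)) {
      h <- gsub(paste0("[ \t]denofo=", TOKEN_RX), "", lines[i])
      lines[i] <- paste0(h, " denofo=", token)
    }
  }
  warn_unmatched(sel, seen)
  parts$lines <- lines
  out <- join_lines(parts)
  if (!is.null(path)) return(write_text(out, path))
  out
}

fasta_token_table <- function(input) {
  parts <- split_keep_trailing(carrier_text(input))
  lines <- parts$lines
  idx <- which(startsWith(lines, ">"))
  ids <- vapply(lines[idx], fasta_id, "", USE.NAMES = FALSE)
  toks <- vapply(lines[idx], function(h) {
    m <- regmatches(h, gregexpr(paste0("denofo=", TOKEN_RX), h))[[1]]
    if (length(m)) sub("^denofo=", "", m[length(m)]) else NA_character_
  }, "", USE.NAMES = FALSE)
  data.frame(id = ids, token = toks, stringsAsFactors = FALSE)
}

decode_for_record <- function(token, record) {
  tryCatch(decode_shortcode(token),
           dnf_decode_error = function(e) stop_integrity(
             sprintf("record '%s' carries an undecodable denofo token: %s",
                     record, conditionMessage(e)), record = record))
}

#' Extract annotations from an annotated FASTA
#'
#' @param input FASTA file path or text.
#' @return A named list mapping each record id that carries a `denofo=`
#'   token to its decoded canonical annotation; tokenless records are
#'   absent.
#' @export
extract_fasta <- function(input) {
  tab <- fasta_token_table(input)
  tab <- tab[!is.na(tab$token), , drop = FALSE]
  out <- lapply(seq_len(nrow(tab)),
                function(i) decode_for_record(tab$token[i], tab$id[i]))
  names(out) <- tab$id
  out
}

gff_feature_id <- function(cols) {
  m <- regmatches(cols[9], regexec("(?:^|;)ID=([^;]*)", cols[9]))[[1]]
  if (length(m) == 2L && nzchar(m[2])) m[2]
  else sprintf("%s:%s-%s", cols[1], cols[4], cols[5])
}

gff_rows <- function(lines) {
  feat <- !startsWith(lines, "#") & nzchar(trimws(lines))
  for (i in which(feat)) {
    if (length(strsplit(lines[i], "\t", fixed = TRUE)[[1]]) != 9L)
      stop_parse(sprintf("GFF3 line %d does not have 9 tab-separated columns", i))
  }
  which(feat)
}

#' Embed an annotation in GFF3 attribute columns
#'
#' Adds `denofo=<shortcode>` to column 9 of each selected feature line,
#' replacing any existing denofo attribute. Columns 1-8, comment and
#' directive lines are untouched byte-for-byte. The shortcode alphabet
#' contains none of `; = % ,`, so the attribute needs no escaping under the
#' GFF3 grammar.
#'
#' @inheritParams annotate_fasta
#' @param input GFF3 file path or text.
#' @return The annotated GFF3 text (invisibly when `path` is given).
#' @seealso [extract_gff()]
#' @export
annotate_gff <- function(input, ann, sel = select_all(), path = NULL) {
  token <- encode_shortcode(ann)
  parts <- split_keep_trailing(carrier_text(input))
  lines <- parts$lines
  seen <- character(0)
  for (i in gff_rows(lines)) {
    cols <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    id <- gff_feature_id(cols)
    seen <- c(seen, id)
    if (selected(sel, id)) {
      attrs <- strsplit(cols[9], ";", fixed = TRUE)[[1]]
      attrs <- attrs[nzchar(attrs) & attrs != "." &
                       !startsWith(attrs, "denofo=")]
      cols[9] <- paste(c(attrs, paste0("denofo=", token)), collapse = ";")
      lines[i] <- paste(cols, collapse = "\t")
    }
  }
  warn_unmatched(sel, seen)
  parts$lines <- lines
  out <- join_lines(parts)
  if (!is.null(path)) return(write_text(out, path))
  out
}

gff_token_table <- function(input) {
  parts <- split_keep_trailing(carrier_text(input))
  lines <- parts$lines
  idx <- gff_rows(lines)
  ids <- character(0); toks <- character(0)
  for (i in idx) {
    cols <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    attrs <- strsplit(cols[9], ";", fixed = TRUE)[[1]]
    tok <- sub("^denofo=", "", grep("^denofo=", attrs, value = TRUE))
    ids <- c(ids, gff_feature_id(cols))
    toks <- c(toks, if (length(tok)) tok[length(tok)] else NA_character_)
  }
  data.frame(id = ids, token = toks, stringsAsFactors = FALSE)
}

#' Extract annotations from an annotated GFF3
#'
#' @param input GFF3 file path or text.
#' @return A named list mapping each feature id whose column 9 carries a
#'   `denofo` attribute to its decoded canonical annotation. Features
#'   sharing an id are reported under one key, with a duplicate-id warning.
#' @export
extract_gff <- function(input) {
  tab <- gff_token_table(input)
  tab <- tab[!is.na(tab$token), , drop = FALSE]
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    warning("duplicate feature id(s) in GFF: ", paste(dup, collapse = ", "),
            call. = FALSE)
  tab <- tab[!duplicated(tab$id), , drop = FALSE]
  out <- lapply(seq_len(nrow(tab)),
                function(i) decode_for_record(tab$token[i], tab$id[i]))
  names(out) <- tab$id
  out
}

#' Convert the annotation between file types
#'
#' The converter moves a methodology annotation between its three homes:
#' the standalone `.dngf` document, FASTA headers and GFF3 attributes.
#' `dngf -> carrier` encodes and embeds; `carrier -> dngf` extracts (all
#' embedded annotations must agree) and writes the document;
#' `carrier -> carrier` extracts from one file and embeds into another.
#'
#' @param input Path to (or text of) the annotation source.
#' @param from,to One of `"dngf"`, `"fasta"`, `"gff"`.
#' @param carrier Path to (or text of) the FASTA/GFF file to annotate;
#'   required whenever `to` is a carrier kind.
#' @param sel Record selection applied when annotating a carrier.
#' @param path Optional output path.
#' @return The output text (invisibly when `path` is given).
#' @export
convert <- function(input, from = c("dngf", "fasta", "gff"),
                    to = c("dngf", "fasta", "gff"), carrier = NULL,
                    sel = select_all(), path = NULL) {
  from <- match.arg(from)
  to <- match.arg(to)
  ann <- switch(from,
    dngf = read_dngf(input),
    fasta = single_annotation(fasta_token_table(input), "FASTA"),
    gff = single_annotation(gff_token_table(input), "GFF"))
  if (to == "dngf") return(write_dngf(ann, path))
  if (is.null(carrier))
    stop(dnf_error(sprintf("converting to %s requires a carrier file", to),
                   "dnf_usage_error"))
  switch(to,
         fasta = annotate_fasta(carrier, ann, sel, path),
         gff = annotate_gff(carrier, ann, sel, path))
}

single_annotation <- function(tab, what) {
  tab <- tab[!is.na(tab$token), , drop = FALSE]
  if (nrow(tab) == 0L)
    stop(dnf_error(sprintf("nothing to extract: %s carries no denofo tokens",
                           what), "dnf_extract_error"))
  anns <- lapply(seq_len(nrow(tab)),
                 function(i) decode_for_record(tab$token[i], tab$id[i]))
  keys <- vapply(anns, write_dngf, "")
  if (length(unique(keys)) > 1L) {
    groups <- split(tab$id, keys)
    stop(dnf_error(paste0(
      "conflicting denofo annotations in ", what, "; differing record ids: ",
      paste(vapply(groups, function(g) paste(g, collapse = ","), ""),
            collapse = " | ")), "dnf_conflict_error"))
  }
  anns[[1]]
}
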