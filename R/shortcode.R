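#' Compact carrier-safe encoding of an annotation
#'
#' A shortcode packs a whole annotation into one token of the form
#' `DNF<codec digit>:<payload>` whose alphabet is restricted to
#' `A-Z a-z 0-9 . _ - :` — none of `; = % , >` or whitespace — so it can sit
#' in a FASTA header or a GFF3 attribute column without escaping. The wire
#' format serializes the canonical form field by field: predefined terms as
#' variable-length integers indexing the frozen vocabulary order, custom
#' strings as length-prefixed UTF-8, thresholds as exact decimal strings.
#' The byte stream is DEFLATE-compressed when that shortens it, a 16-bit
#' CRC is appended, and the result is base64url-encoded without padding.
#' Encoding is deterministic; single-character corruption of a token is
#' detected by the checksum.
#'
#' @param ann A valid annotation.
#' @return A single string beginning with `"DNF1:"`.
#' @seealso [decode_shortcode()]
#' @examples
#' ann <- denofo_annotation(
#'   dnf_input_data("genome_annotation"),
#'   dnf_evolutionary_information("synteny_based"),
#'   dnf_homology_filter(dnf_tool("diamond"), "no_hit_beyond_focal_clade")
#' )
#' code <- encode_shortcode(ann)
#' code
#' identical(decode_shortcode(code), canonicalize(ann))
#' @export
encode_shortcode <- function(ann) {
  ann <- canonicalize(ann)
  payload <- serialize_annotation(ann)
  comp <- memCompress(payload, type = "gzip")
  body <- if (length(comp) < length(payload)) c(as.raw(1L), comp)
          else c(as.raw(0L), payload)
  crc <- crc16(body)
  bytes <- c(body, as.raw(bitwShiftR(crc, 8)), as.raw(bitwAnd(crc, 255L)))
  paste0("DNF", SHORTCODE_VERSION, ":",
         gsub("[\r\n]", "", jsonlite::base64url_enc(bytes)))
}

#' Decode a shortcode back into an annotation
#'
#' @param code A token produced by [encode_shortcode()].
#' @return The canonical `denofo_annotation` the token encodes.
#' @section Errors:
#' A token with a wrong prefix or an unsupported codec digit signals a
#' `dnf_version_error`; a corrupted payload (invalid character, truncation,
#' checksum mismatch, malformed byte stream) signals a
#' `dnf_integrity_error`. Both inherit from `dnf_decode_error`; a corrupted
#' token is never decoded into a silently wrong annotation.
#' @export
decode_shortcode <- function(code) {
  if (!is.character(code) || length(code) != 1L)
    stop_integrity("shortcode must be a single string")
  m <- regmatches(code, regexec("^DNF([0-9]):(.*)$", code))[[1]]
  if (length(m) != 3L)
    stop_version("not a DeNoFo shortcode (expected prefix 'DNF<digit>:')",
                 found = code)
  if (m[2] != SHORTCODE_VERSION)
    stop_version(sprintf(
      "unsupported shortcode codec version %s (this build supports version %s)",
      m[2], SHORTCODE_VERSION), found = m[2], supported = SHORTCODE_VERSION)
  payload <- m[3]
  if (!grepl("^[A-Za-z0-9_-]+$", payload))
    stop_integrity("shortcode payload contains characters outside the token alphabet")
  bytes <- tryCatch(jsonlite::base64url_dec(payload),
                    error = function(e) stop_integrity(
                      paste0("undecodable shortcode payload: ",
                             conditionMessage(e))))
  if (length(bytes) < 4L)
    stop_integrity("shortcode payload truncated")
  # Base64 is not injective on its final character's unused bits; insist on
  # the canonical encoding so every single-character mutation is rejected.
  if (!identical(gsub("[\r\n]", "", jsonlite::base64url_enc(bytes)), payload))
    stop_integrity("non-canonical shortcode encoding (token corrupted)")
  n <- length(bytes)
  body <- bytes[1:(n - 2L)]
  stored <- bitwShiftL(as.integer(bytes[n - 1L]), 8) + as.integer(bytes[n])
  if (stored != crc16(body))
    stop_integrity("shortcode checksum mismatch (token corrupted)")
  flag <- as.integer(body[1])
  raw_payload <- tryCatch({
    if (flag == 1L) memDecompress(body[-1], type = "gzip")
    else if (flag == 0L) body[-1]
    else stop("bad compression flag")
  }, error = function(e) stop_integrity(
    paste0("shortcode payload does not decompress: ", conditionMessage(e))))
  ann <- tryCatch(
    canonicalize(deserialize_annotation(raw_payload)),
    error = function(e) stop_integrity(
      paste0("shortcode payload is not a valid annotation: ",
             conditionMessage(e))))
  ann
}

SHORTCODE_VERSION <- "1"

# ---- byte stream primitives ------------------------------------------------

varint_bytes <- function(x) {
  x <- as.integer(x)
  out <- raw(0)
  repeat {
    b <- bitwAnd(x, 127L)
    x <- bitwShiftR(x, 7L)
    if (x > 0L) out <- c(out, as.raw(bitwOr(b, 128L)))
    else return(c(out, as.raw(b)))
  }
}

str_bytes <- function(s) {
  b <- charToRaw(enc2utf8(s))
  c(varint_bytes(length(b)), b)
}

new_reader <- function(bytes) {
  pos <- 1L
  take <- function(k) {
    if (pos + k - 1L > length(bytes)) stop("byte stream truncated")
    out <- bytes[pos:(pos + k - 1L)]
    pos <<- pos + k
    out
  }
  list(
    byte = function() as.integer(take(1L)),
    varint = function() {
      x <- 0L; shift <- 0L
      repeat {
        b <- as.integer(take(1L))
        x <- bitwOr(x, bitwShiftL(bitwAnd(b, 127L), shift))
        if (b < 128L) return(x)
        shift <- shift + 7L
        if (shift > 28L) stop("varint overflow")
      }
    },
    string = function() {
      n <- 0L; shift <- 0L
      repeat {
        b <- as.integer(take(1L))
        n <- bitwOr(n, bitwShiftL(bitwAnd(b, 127L), shift))
        if (b < 128L) break
        shift <- shift + 7L
        if (shift > 28L) stop("varint overflow")
      }
      s <- rawToChar(take(n))
      Encoding(s) <- "UTF-8"
      if (!validUTF8(s)) stop("invalid UTF-8 in byte stream")
      s
    },
    done = function() pos > length(bytes)
  )
}

# ---- annotation <-> bytes --------------------------------------------------

choice_bytes <- function(x, vocabulary) {
  if (x$kind == "predefined")
    c(as.raw(0L), varint_bytes(vocab_index(vocabulary, x$term)))
  else c(as.raw(1L), str_bytes(x$text))
}

read_choice <- function(r, vocabulary) {
  tag <- r$byte()
  if (tag == 0L) {
    term <- vocab_term_at(vocabulary, r$varint())
    if (is.na(term)) stop("vocabulary index out of range")
    dnf_predefined(vocabulary, term)
  } else if (tag == 1L) {
    dnf_custom(r$string())
  } else stop("bad choice tag")
}

choice_list_bytes <- function(xs, vocabulary) {
  c(varint_bytes(length(xs)),
    unlist(lapply(xs, choice_bytes, vocabulary = vocabulary)))
}

read_choice_list <- function(r, vocabulary) {
  n <- r$varint()
  if (n > 10000L) stop("implausible list length")
  lapply(seq_len(n), function(i) read_choice(r, vocabulary))
}

tool_bytes <- function(t) {
  flags <- bitwOr(bitwOr(
    if (!is.null(t$database)) 1L else 0L,
    if (!is.null(t$evalue_threshold)) 2L else 0L),
    if (!is.null(t$coverage_threshold)) 4L else 0L)
  c(choice_bytes(t$tool, "homology_tools"), as.raw(flags),
    if (!is.null(t$database)) str_bytes(t$database),
    if (!is.null(t$evalue_threshold)) str_bytes(num_to_str(t$evalue_threshold)),
    if (!is.null(t$coverage_threshold))
      str_bytes(num_to_str(t$coverage_threshold)))
}

read_tool <- function(r) {
  tool <- read_choice(r, "homology_tools")
  flags <- r$byte()
  list(tool = tool,
       database = if (bitwAnd(flags, 1L) > 0L) r$string(),
       evalue_threshold = if (bitwAnd(flags, 2L) > 0L) as.numeric(r$string()),
       coverage_threshold = if (bitwAnd(flags, 4L) > 0L) as.numeric(r$string()))
}

serialize_annotation <- function(ann) {
  id <- ann$input_data
  ei <- ann$evolutionary_information
  hf <- ann$homology_filter
  presence <- bitwOr(bitwOr(
    if (!is.null(ann$non_coding_homologs)) 1L else 0L,
    if (!is.null(ann$lab_verification)) 2L else 0L),
    if (!is.null(ann$hyperlinks)) 4L else 0L)
  id_flags <- bitwOr(
    if (!is.null(id$orf_definition)) 1L else 0L,
    if (!is.null(id$minimum_orf_length_codons)) 2L else 0L)
  ei_flags <- bitwOr(
    if (!is.null(ei$outgroup_count)) 1L else 0L,
    if (!is.null(ei$phylogeny_source)) 2L else 0L)
  c(str_bytes(ann$format_version),
    as.raw(presence),
    choice_list_bytes(id$candidate_sources, "candidate_sources"),
    as.raw(id_flags),
    if (!is.null(id$orf_definition))
      choice_bytes(id$orf_definition, "orf_definition"),
    if (!is.null(id$minimum_orf_length_codons))
      varint_bytes(id$minimum_orf_length_codons),
    choice_bytes(ei$age_inference, "age_inference"),
    as.raw(ei_flags),
    if (!is.null(ei$outgroup_count)) varint_bytes(ei$outgroup_count),
    if (!is.null(ei$phylogeny_source))
      choice_bytes(ei$phylogeny_source, "phylogeny_source"),
    varint_bytes(length(hf$searches)),
    unlist(lapply(hf$searches, tool_bytes)),
    choice_bytes(hf$homology_criterion, "homology_criterion"),
    if (!is.null(ann$non_coding_homologs)) c(
      as.raw(as.integer(ann$non_coding_homologs$required_for_classification)),
      choice_list_bytes(ann$non_coding_homologs$detection_methods,
                        "noncoding_detection")),
    if (!is.null(ann$lab_verification)) c(
      choice_list_bytes(ann$lab_verification$transcription_evidence,
                        "transcription_evidence"),
      choice_list_bytes(ann$lab_verification$translation_evidence,
                        "translation_evidence")),
    if (!is.null(ann$hyperlinks)) c(
      varint_bytes(length(ann$hyperlinks$links)),
      unlist(lapply(ann$hyperlinks$links, function(l)
        c(as.raw(if (l$kind == "doi") 1L else 0L), str_bytes(l$value)))))
  )
}

deserialize_annotation <- function(bytes) {
  r <- new_reader(bytes)
  fv <- r$string()
  presence <- r$byte()
  candidate_sources <- read_choice_list(r, "candidate_sources")
  id_flags <- r$byte()
  orf_definition <- if (bitwAnd(id_flags, 1L) > 0L)
    read_choice(r, "orf_definition")
  min_orf <- if (bitwAnd(id_flags, 2L) > 0L) r$varint()
  age_inference <- read_choice(r, "age_inference")
  ei_flags <- r$byte()
  outgroup_count <- if (bitwAnd(ei_flags, 1L) > 0L) r$varint()
  phylogeny_source <- if (bitwAnd(ei_flags, 2L) > 0L)
    read_choice(r, "phylogeny_source")
  n_search <- r$varint()
  if (n_search > 1000L) stop("implausible search count")
  searches <- lapply(seq_len(n_search), function(i) read_tool(r))
  homology_criterion <- read_choice(r, "homology_criterion")
  ncs <- if (bitwAnd(presence, 1L) > 0L) {
    req <- r$byte()
    if (req > 1L) stop("bad boolean byte")
    list(required_for_classification = req == 1L,
         detection_methods = read_choice_list(r, "noncoding_detection"))
  }
  lab <- if (bitwAnd(presence, 2L) > 0L) {
    list(transcription_evidence = read_choice_list(r, "transcription_evidence"),
         translation_evidence = read_choice_list(r, "translation_evidence"))
  }
  links <- if (bitwAnd(presence, 4L) > 0L) {
    n <- r$varint()
    if (n > 10000L) stop("implausible link count")
    list(links = lapply(seq_len(n), function(i) {
      kind <- r$byte()
      if (kind > 1L) stop("bad link kind byte")
      list(kind = if (kind == 1L) "doi" else "url", value = r$string())
    }))
  }
  if (!r$done()) stop("trailing bytes after annotation")
  list(format_version = fv,
       input_data = list(candidate_sources = candidate_sources,
                         orf_definition = orf_definition,
                         minimum_orf_length_codons = min_orf),
       evolutionary_information = list(age_inference = age_inference,
                                       outgroup_count = outgroup_count,
                                       phylogeny_source = phylogeny_source),
       homology_filter = list(searches = searches,
                              homology_criterion = homology_criterion),
       non_coding_homologs = ncs,
       lab_verification = lab,
       hyperlinks = links)
}

# ---- CRC-16/CCITT-FALSE ----------------------------------------------------

crc16_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- integer(256)
      for (i in 0:255) {
        c <- bitwShiftL(i, 8)
        for (j in 1:8) {
          c <- if (bitwAnd(c, 32768L) > 0L)
            bitwXor(bitwAnd(bitwShiftL(c, 1), 65535L), 4129L)
          else bitwAnd(bitwShiftL(c, 1), 65535L)
        }
        t[i + 1L] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc16 <- function(bytes) {
  tab <- crc16_table()
  crc <- 65535L
  for (b in as.integer(bytes)) {
    idx <- bitwXor(bitwShiftR(crc, 8), b)
    crc <- bitwAnd(bitwXor(bitwShiftL(crc, 8), tab[idx + 1L]), 65535L)
  }
  crc
}
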