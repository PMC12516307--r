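# Seeded generators of random valid annotations and toy FASTA/GFF carriers.
# Every generator is a pure function of its arguments: the global RNG state
# is saved and restored around each call, so fixtures never leak randomness
# into, or absorb randomness from, the caller.

with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Fixture generator configuration
#'
#' @param seed Integer seed; identical configurations yield identical
#'   fixtures.
#' @param p_custom Probability that a choice field takes a custom free-text
#'   answer instead of a predefined term.
#' @param p_optional Probability that each optional section (and each
#'   optional field) is present.
#' @param adversarial_text If `TRUE`, custom answers are drawn from a pool
#'   of codec-hostile strings: `;`, `=`, `%`, `,`, tabs, newlines, emoji,
#'   CJK text and kilobyte-long strings.
#' @return A `dnf_fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, p_custom = 0.3, p_optional = 0.5,
                           adversarial_text = FALSE) {
  stopifnot(p_custom >= 0, p_custom <= 1, p_optional >= 0, p_optional <= 1)
  structure(list(seed = as.integer(seed), p_custom = p_custom,
                 p_optional = p_optional,
                 adversarial_text = isTRUE(adversarial_text)),
            class = "dnf_fixture_config")
}

adversarial_pool <- function() {
  c("50% coverage; e=10-5", "a=b;c=d", "tab\there", "line\nbreak",
    "comma, separated, values", "α; e=1", "基因组",
    "\U0001F9EC de novo", "  padded  ", "percent 100%",
    strrep("x", 1000), ">fake_header", "key=value%20encoded")
}

plain_pool <- function() {
  c("custom pipeline v2", "in-house script", "manual curation",
    "lab protocol 7", "modified published workflow")
}

#' Generate a random valid annotation
#'
#' Draws one annotation whose choice fields mix predefined vocabulary terms
#' and custom answers according to the configuration. The result always
#' passes [validate_annotation()].
#'
#' @param cfg A [fixture_config()].
#' @return A valid `denofo_annotation`.
#' @examples
#' ann <- generate_annotation(fixture_config(seed = 42))
#' validate_annotation(ann)$valid
#' @export
generate_annotation <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "dnf_fixture_config"))
  with_local_seed(cfg$seed, {
    pool <- if (cfg$adversarial_text) adversarial_pool() else plain_pool()
    rchoice <- function(vocabulary, exclude = character(0)) {
      if (runif(1) < cfg$p_custom) {
        dnf_custom(sample(pool, 1L))
      } else {
        terms <- setdiff(dnf_vocabularies()[[vocabulary]], exclude)
        dnf_predefined(vocabulary, sample(terms, 1L))
      }
    }
    rchoice_list <- function(vocabulary, max_n = 3L, none_exclusive = FALSE) {
      n <- sample.int(max_n, 1L)
      out <- list()
      used <- character(0)
      for (i in seq_len(n)) {
        ch <- rchoice(vocabulary,
                      exclude = c(used, if (none_exclusive && i > 1L) "none"))
        if (ch$kind == "predefined") {
          if (none_exclusive && ch$term == "none" && length(out) > 0L) next
          used <- c(used, ch$term)
        }
        out <- c(out, list(ch))
        if (none_exclusive && ch$kind == "predefined" && ch$term == "none")
          break
      }
      out
    }
    maybe <- function(x) if (runif(1) < cfg$p_optional) x else NULL

    input_data <- list(
      candidate_sources = rchoice_list("candidate_sources"),
      orf_definition = maybe(rchoice("orf_definition")),
      minimum_orf_length_codons = maybe(sample(c(10L, 30L, 50L, 100L), 1L)))
    evo <- list(
      age_inference = rchoice("age_inference"),
      outgroup_count = maybe(sample(0:12, 1L)),
      phylogeny_source = maybe(rchoice("phylogeny_source")))
    n_tools <- sample.int(3L, 1L)
    searches <- lapply(seq_len(n_tools), function(i) {
      dnf_tool(rchoice("homology_tools"),
               database = maybe(sample(c("nr 2024-01", "uniref90 2023_05",
                                         "refseq_protein 224"), 1L)),
               evalue_threshold = maybe(sample(c(1e-3, 1e-5, 1e-10), 1L)),
               coverage_threshold = maybe(sample(c(0.5, 0.7, 0.9), 1L)))
    })
    hf <- list(searches = searches,
               homology_criterion = rchoice("homology_criterion"))
    ncs <- if (runif(1) < cfg$p_optional) {
      req <- runif(1) < 0.5
      list(required_for_classification = req,
           detection_methods = if (req || runif(1) < 0.5)
             rchoice_list("noncoding_detection") else list())
    }
    lab <- if (runif(1) < cfg$p_optional) {
      list(transcription_evidence =
             rchoice_list("transcription_evidence", none_exclusive = TRUE),
           translation_evidence =
             rchoice_list("translation_evidence", none_exclusive = TRUE))
    }
    links <- if (runif(1) < cfg$p_optional) {
      n <- sample.int(3L, 1L)
      list(links = lapply(seq_len(n), function(i) {
        if (runif(1) < 0.5)
          dnf_link(sprintf("10.%d/denofo.fix.%d", sample(1000:9999, 1L), i))
        else dnf_link(sprintf("https://example.org/study/%d",
                              sample.int(1000000L, 1L)))
      }))
    }
    denofo_annotation(input_data, evo, hf, non_coding_homologs = ncs,
                      lab_verification = lab, hyperlinks = links)
  })
}

#' Generate a toy FASTA carrier
#'
#' @param seed Integer seed.
#' @param n_records Number of records (ids `seq1` .. `seqN`).
#' @param seq_length Sequence length in bases.
#' @return FASTA text as a single string (records wrapped at 60 columns).
#' @export
generate_fasta <- function(seed = 1L, n_records = 3L, seq_length = 120L) {
  stopifnot(n_records >= 1L, seq_length >= 1L)
  with_local_seed(seed, {
    recs <- vapply(seq_len(n_records), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), seq_length, replace = TRUE),
                 collapse = "")
      wrapped <- substring(s, seq(1L, seq_length, 60L),
                           pmin(seq(1L, seq_length, 60L) + 59L, seq_length))
      paste0(">seq", i, " toy record ", i, "\n",
             paste(wrapped, collapse = "\n"))
    }, "")
    paste0(paste(recs, collapse = "\n"), "\n")
  })
}

#' Generate a toy GFF3 carrier
#'
#' @param seed Integer seed.
#' @param n_features Number of gene features (ids `dnG001` ..).
#' @return GFF3 text as a single string, starting with the
#'   `##gff-version 3` directive.
#' @export
generate_gff <- function(seed = 1L, n_features = 5L) {
  stopifnot(n_features >= 1L)
  with_local_seed(seed, {
    lines <- vapply(seq_len(n_features), function(i) {
      start <- sample(1:100000, 1L)
      end <- start + sample(100:5000, 1L)
      strand <- sample(c("+", "-"), 1L)
      sprintf("chr%d\tdenofor\tgene\t%d\t%d\t.\t%s\t.\tID=dnG%03d;Name=toy%d",
              sample(1:5, 1L), start, end, strand, i, i)
    }, "")
    paste0("##gff-version 3\n", paste(lines, collapse = "\n"), "\n")
  })
}
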