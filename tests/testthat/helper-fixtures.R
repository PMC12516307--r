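# Shared fixture builders and an independent invariant oracle.

# Deterministic fully-populated annotation with known values (all six
# sections present, predefined terms only).
base_full_annotation <- function() {
  denofo_annotation(
    dnf_input_data(c("genome_annotation", "transcriptome_assembly"),
                   orf_definition = "start_to_stop",
                   minimum_orf_length_codons = 30L),
    dnf_evolutionary_information("phylostratigraphy", outgroup_count = 6L,
                                 phylogeny_source = "published_tree"),
    dnf_homology_filter(
      list(dnf_tool("blast", database = "nr 2024-01",
                    evalue_threshold = 1e-5, coverage_threshold = 0.5),
           dnf_tool("hmmer", evalue_threshold = 1e-3)),
      "no_hit_in_any_outgroup"),
    non_coding_homologs = dnf_non_coding_homologs(TRUE, list("synteny_alignment")),
    lab_verification = dnf_lab_verification(list("rnaseq", "rt_pcr"),
                                            list("riboseq")),
    hyperlinks = dnf_hyperlinks(c("10.1000/denofo.base",
                                  "https://example.org/study"))
  )
}

minimal_annotation <- function() {
  denofo_annotation(
    dnf_input_data("ribosome_profiling"),
    dnf_evolutionary_information("synteny_based"),
    dnf_homology_filter(dnf_tool("diamond"), "no_hit_beyond_focal_clade"))
}

# Single-invariant mutations of a valid annotation, named by the field path
# each one breaks. Each takes and returns an unclassed annotation list.
invariant_mutations <- function() {
  list(
    "homology_filter" = function(a) { a["homology_filter"] <- list(NULL); a },
    "input_data.candidate_sources" = function(a) {
      a$input_data$candidate_sources <-
        c(a$input_data$candidate_sources,
          a$input_data$candidate_sources[1])  # duplicate predefined term
      a
    },
    "input_data.minimum_orf_length_codons" = function(a) {
      a$input_data$minimum_orf_length_codons <- -3L
      a
    },
    "evolutionary_information.outgroup_count" = function(a) {
      a$evolutionary_information$outgroup_count <- -1L
      a
    },
    "homology_filter.searches[1].evalue_threshold" = function(a) {
      a$homology_filter$searches[[1]]$evalue_threshold <- -1e-5
      a
    },
    "homology_filter.searches[1].coverage_threshold" = function(a) {
      a$homology_filter$searches[[1]]$coverage_threshold <- 1.5
      a
    },
    "non_coding_homologs.detection_methods" = function(a) {
      a$non_coding_homologs$detection_methods <- list()
      a
    },
    "lab_verification.transcription_evidence" = function(a) {
      a$lab_verification$transcription_evidence <-
        list(dnf_predefined("transcription_evidence", "none"),
             dnf_predefined("transcription_evidence", "rnaseq"))
      a
    },
    "hyperlinks.links[1]" = function(a) {
      a$hyperlinks$links[[1]] <- dnf_link("not-a-doi", kind = "doi")
      a
    }
  )
}

# Independent brute-force oracle: re-checks every schema invariant with its
# own direct logic and returns the set of violated field paths (prefixes).
oracle_violation_paths <- function(a) {
  bad <- character(0)
  hit <- function(p) bad <<- c(bad, p)
  vocab <- dnf_vocabularies()
  choice_ok <- function(ch, voc) {
    if (!is.list(ch) || is.null(ch$kind)) return(FALSE)
    if (ch$kind == "predefined")
      identical(ch$vocabulary, voc) && ch$term %in% vocab[[voc]]
    else nzchar(trimws(ch$text %||% ""))
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (sec in c("input_data", "evolutionary_information", "homology_filter"))
    if (is.null(a[[sec]])) hit(sec)
  id <- a$input_data
  if (!is.null(id)) {
    cs <- id$candidate_sources %||% list()
    if (length(cs) < 1) hit("input_data.candidate_sources")
    terms <- unlist(lapply(cs, function(c)
      if (identical(c$kind, "predefined")) c$term))
    if (anyDuplicated(terms)) hit("input_data.candidate_sources")
    for (i in seq_along(cs)) if (!choice_ok(cs[[i]], "candidate_sources"))
      hit(sprintf("input_data.candidate_sources[%d]", i))
    m <- id$minimum_orf_length_codons
    if (!is.null(m) && (!is.numeric(m) || m < 1 || m != floor(m)))
      hit("input_data.minimum_orf_length_codons")
  }
  ei <- a$evolutionary_information
  if (!is.null(ei)) {
    if (!choice_ok(ei$age_inference %||% list(), "age_inference"))
      hit("evolutionary_information.age_inference")
    o <- ei$outgroup_count
    if (!is.null(o) && (!is.numeric(o) || o < 0 || o != floor(o)))
      hit("evolutionary_information.outgroup_count")
  }
  hf <- a$homology_filter
  if (!is.null(hf)) {
    if (length(hf$searches %||% list()) < 1) hit("homology_filter.searches")
    for (i in seq_along(hf$searches)) {
      t <- hf$searches[[i]]
      if (!is.null(t$evalue_threshold) && t$evalue_threshold <= 0)
        hit(sprintf("homology_filter.searches[%d].evalue_threshold", i))
      if (!is.null(t$coverage_threshold) &&
          (t$coverage_threshold < 0 || t$coverage_threshold > 1))
        hit(sprintf("homology_filter.searches[%d].coverage_threshold", i))
    }
  }
  n <- a$non_coding_homologs
  if (!is.null(n) && isTRUE(n$required_for_classification) &&
      length(n$detection_methods %||% list()) == 0)
    hit("non_coding_homologs.detection_methods")
  lv <- a$lab_verification
  if (!is.null(lv)) {
    for (f in c("transcription_evidence", "translation_evidence")) {
      terms <- unlist(lapply(lv[[f]] %||% list(), function(c)
        if (identical(c$kind, "predefined")) c$term))
      if ("none" %in% terms && length(lv[[f]]) > 1)
        hit(paste0("lab_verification.", f))
    }
  }
  hy <- a$hyperlinks
  if (!is.null(hy)) for (i in seq_along(hy$links)) {
    l <- hy$links[[i]]
    ok <- if (identical(l$kind, "doi")) grepl("^10\\.[0-9]+/.+", l$value)
    else if (identical(l$kind, "url")) grepl("://", l$value) else FALSE
    if (!ok) hit(sprintf("hyperlinks.links[%d]", i))
  }
  unique(bad)
}

# Random driver for the questionnaire state machine; answers every question
# with a type-correct value drawn under the seed.
fuzz_questionnaire <- function(seed) {
  set.seed(seed)
  st <- build_questionnaire()
  steps <- 0L
  while (!is.null(q <- current_question(st)) && steps < 200L) {
    steps <- steps + 1L
    if (runif(1) < 0.1) {  # occasional back-navigation
      st <- tryCatch(go_back(st), dnf_navigation_error = function(e) st)
      next
    }
    value <- switch(q$answer_kind,
      boolean = runif(1) < 0.5,
      integer = if (runif(1) < 0.3) NULL else sample(c(1L, 5L, 30L), 1L),
      text = "10.1234/fuzz https://example.org/fuzz",
      single_choice = if (!q$required && runif(1) < 0.3) NULL
        else if (runif(1) < 0.2) "a custom answer"
        else sample(q$options, 1L),
      multi_choice = {
        n <- sample.int(min(2L, length(q$options)), 1L)
        opts <- setdiff(q$options, "none")
        as.list(sample(opts, n))
      })
    st <- answer_current(st, value)
  }
  st
}

strip_fasta_tokens <- function(text) {
  gsub(" denofo=DNF[0-9]:[A-Za-z0-9._-]+", "", text)
}

strip_gff_tokens <- function(text) {
  gsub(";?denofo=DNF[0-9]:[A-Za-z0-9._-]+", "", text)
}

# Seeded single-character corruptions of a token's payload (after "DNF1:"),
# drawn from the token alphabet so the checksum—not the charset check—is
# what rejects them. Returns the mutated tokens.
corrupt_tokens <- function(code, n, seed) {
  set.seed(seed)
  alphabet <- c(LETTERS, letters, 0:9, "-", "_")
  vapply(seq_len(n), function(i) {
    pos <- sample(6:nchar(code), 1L)
    repl <- sample(alphabet, 1L)
    while (repl == substr(code, pos, pos)) repl <- sample(alphabet, 1L)
    paste0(substr(code, 1L, pos - 1L), repl,
           substr(code, pos + 1L, nchar(code)))
  }, "")
}

# Known single-field edits used for diff-injection; each changes the
# canonical value at exactly one leaf of the fully-populated base fixture.
comparison_edits <- function() {
  list(
    "homology_filter.homology_criterion" = function(a) {
      a$homology_filter$homology_criterion <-
        dnf_predefined("homology_criterion", "no_hit_beyond_focal_clade")
      a
    },
    "evolutionary_information.age_inference" = function(a) {
      a$evolutionary_information$age_inference <-
        dnf_predefined("age_inference", "gene_tree_reconciliation")
      a
    },
    "input_data.minimum_orf_length_codons" = function(a) {
      a$input_data$minimum_orf_length_codons <- 99L
      a
    },
    "lab_verification.transcription_evidence" = function(a) {
      a$lab_verification$transcription_evidence <-
        list(dnf_predefined("transcription_evidence", "cage"))
      a
    },
    "hyperlinks.links" = function(a) {
      a$hyperlinks$links <- list(dnf_link("10.9999/edited"))
      a
    }
  )
}

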