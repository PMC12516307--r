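test_that("annotating FASTA touches only selected headers and preserves all bytes elsewhere", {
  fa <- generate_fasta(seed = 7, n_records = 3, seq_length = 120)
  a <- base_full_annotation()
  out <- annotate_fasta(fa, a)
  token <- encode_shortcode(a)
  headers <- grep("^>", strsplit(out, "\n")[[1]], value = TRUE)
  expect_length(headers, 3L)
  expect_true(all(endsWith(headers, paste0(" denofo=", token))))
  expect_identical(strip_fasta_tokens(out), fa)

  only2 <- annotate_fasta(fa, a, select_ids("seq2"))
  h2 <- grep("^>", strsplit(only2, "\n")[[1]], value = TRUE)
  expect_match(h2[2], "denofo=")
  expect_no_match(h2[1], "denofo=")
  expect_no_match(h2[3], "denofo=")
  expect_identical(strip_fasta_tokens(only2), fa)
})

test_that("re-annotating replaces the existing token instead of duplicating it", {
  fa <- generate_fasta(seed = 1, n_records = 2, seq_length = 60)
  a <- minimal_annotation()
  b <- base_full_annotation()
  twice <- annotate_fasta(annotate_fasta(fa, a), b)
  m <- extract_fasta(twice)
  expect_identical(m$seq1, canonicalize(b))
  headers <- grep("^>", strsplit(twice, "\n")[[1]], value = TRUE)
  expect_true(all(lengths(regmatches(headers, gregexpr("denofo=", headers))) == 1L))
})

test_that("FASTA extraction maps every tokened record and flags broken tokens by record", {
  fa <- generate_fasta(seed = 3, n_records = 3, seq_length = 90)
  a <- minimal_annotation()
  out <- annotate_fasta(fa, a)
  m <- extract_fasta(out)
  expect_named(m, c("seq1", "seq2", "seq3"))
  for (ann in m) expect_identical(ann, canonicalize(a))
  expect_length(extract_fasta(fa), 0L)
  # truncate seq2's token by hand
  lines <- strsplit(out, "\n")[[1]]
  i <- grep("^>seq2", lines)
  lines[i] <- substr(lines[i], 1, nchar(lines[i]) - 10L)
  err <- expect_error(extract_fasta(paste(lines, collapse = "\n")),
                      class = "dnf_integrity_error")
  expect_match(conditionMessage(err), "seq2")
})

test_that("selection diagnostics and malformed carriers are reported", {
  fa <- generate_fasta(seed = 2, n_records = 2, seq_length = 30)
  expect_warning(annotate_fasta(fa, minimal_annotation(),
                                select_ids(c("seq1", "ghost"))), "ghost")
  expect_error(annotate_fasta("ACGT\nACGT", minimal_annotation()),
               class = "dngf_parse_error")
  expect_error(annotate_gff("##gff-version 3\nchr1\tonly\tthree", minimal_annotation()),
               class = "dngf_parse_error")
})

test_that("annotating GFF3 edits only column 9 of selected features", {
  g <- generate_gff(seed = 3, n_features = 5)
  a <- base_full_annotation()
  out <- annotate_gff(g, a)
  gl <- strsplit(g, "\n")[[1]]
  ol <- strsplit(out, "\n")[[1]]
  expect_identical(ol[1], "##gff-version 3")
  for (i in 2:6) {
    before <- strsplit(gl[i], "\t")[[1]]
    after <- strsplit(ol[i], "\t")[[1]]
    expect_identical(after[1:8], before[1:8])
    expect_match(after[9], "(^|;)denofo=DNF[0-9]:[A-Za-z0-9._-]+$")
    # appended with a single ';', no empty attribute created
    expect_no_match(after[9], ";;")
  }
  expect_identical(strip_gff_tokens(out), g)

  sel <- annotate_gff(g, a, select_pattern("^dnG00[12]$"))
  sl <- strsplit(sel, "\n")[[1]]
  expect_match(sl[2], "denofo=")
  expect_match(sl[3], "denofo=")
  expect_no_match(sl[4], "denofo=")
})

test_that("GFF extraction mirrors FASTA extraction, with duplicate-id handling", {
  g <- generate_gff(seed = 9, n_features = 4)
  a <- minimal_annotation()
  out <- annotate_gff(g, a)
  m <- extract_gff(out)
  expect_named(m, sprintf("dnG%03d", 1:4))
  for (ann in m) expect_identical(ann, canonicalize(a))
  expect_length(extract_gff(g), 0L)

  dupline <- sub("ID=dnG002", "ID=dnG001", out)
  expect_warning(md <- extract_gff(dupline), "dnG001")
  expect_identical(length(md), 3L)

  # feature without an ID attribute falls back to seqid:start-end
  noid <- "##gff-version 3\nchr9\tx\tgene\t100\t200\t.\t+\t.\tNote=anon"
  mn <- extract_gff(annotate_gff(noid, a))
  expect_named(mn, "chr9:100-200")
})

test_that("the converter composes embed and extract across all three kinds", {
  a <- base_full_annotation()
  dngf <- write_dngf(a)
  fa <- generate_fasta(seed = 5, n_records = 3, seq_length = 60)
  g <- generate_gff(seed = 5, n_features = 3)

  annotated_fa <- convert(dngf, "dngf", "fasta", carrier = fa)
  expect_identical(extract_fasta(annotated_fa)$seq1, canonicalize(a))
  back <- convert(annotated_fa, "fasta", "dngf")
  expect_identical(back, dngf)

  annotated_g <- convert(annotated_fa, "fasta", "gff", carrier = g)
  full_cycle <- convert(annotated_g, "gff", "dngf")
  expect_identical(full_cycle, dngf)
})

test_that("converter errors: nothing to extract, conflicts, missing carrier", {
  fa <- generate_fasta(seed = 6, n_records = 2, seq_length = 30)
  expect_error(convert(fa, "fasta", "dngf"), "nothing to extract")
  expect_error(convert(write_dngf(minimal_annotation()), "dngf", "fasta"),
               class = "dnf_usage_error")

  mixed <- annotate_fasta(
    annotate_fasta(fa, minimal_annotation(), select_ids("seq1")),
    base_full_annotation(), select_ids("seq2"))
  err <- expect_error(convert(mixed, "fasta", "dngf"),
                      class = "dnf_conflict_error")
  expect_match(conditionMessage(err), "seq1")
  expect_match(conditionMessage(err), "seq2")
})

test_that("annotated carriers still parse under standard readers", {
  skip_if_not_installed("Biostrings")
  fa_path <- file.path(tempdir(), "carrier.fasta")
  on.exit(unlink(fa_path))
  a <- base_full_annotation()
  annotate_fasta(generate_fasta(seed = 8, n_records = 3, seq_length = 120),
                 a, path = fa_path)
  seqs <- Biostrings::readDNAStringSet(fa_path)
  expect_length(seqs, 3L)
  expect_identical(unique(Biostrings::width(seqs)), 120L)
  expect_true(all(grepl("denofo=DNF1:", names(seqs))))
})
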