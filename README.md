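# denofor

Standardized, machine-comparable methodology annotation for *de novo* gene
studies.

*De novo* genes arise from previously non-genic genomic sequence rather than
by duplication of existing genes. Studies hunting for them differ in almost
every methodological choice — where candidate ORFs come from (annotated
genomes, transcriptome assemblies, ribosome profiling), how gene age is
inferred (phylostratigraphy, synteny, gene-tree reconciliation), which
homology searches and thresholds define "no detectable homolog", whether a
non-coding homologous region in outgroups is required, and what wet-lab
evidence backs transcription and translation. Because of this, *de novo*
gene sets for the same species can disagree by an order of magnitude, and
comparing two studies means re-reading two methods sections.

`denofor` implements the **DeNoFo annotation format**: one validated record
that captures a study's entire detection methodology. The format is
gene-agnostic by design — all genes of a study are covered by a single
methodology record — and has six sections, three of which are mandatory:

| section | required | content |
|---|---|---|
| `input_data` | yes | candidate sources, ORF definition, minimum ORF length |
| `evolutionary_information` | yes | age inference approach, outgroups, phylogeny source |
| `homology_filter` | yes | search tools, databases, E-value/coverage thresholds, homology criterion |
| `non_coding_homologs` | no | whether and how ancestral non-coding homologs were required/located |
| `lab_verification` | no | transcription and translation evidence |
| `hyperlinks` | no | URLs/DOIs for data and protocols |

Most fields take a term from a frozen controlled vocabulary *or* a custom
free-text answer, so unusual pipelines are never forced into ill-fitting
categories while typical ones stay machine-comparable.

The toolkit around the model:

- **`.dngf` documents** (`write_dngf()` / `read_dngf()`) — strict JSON with
  a fixed key order and byte-stable output, human-readable and diffable.
- **Shortcodes** (`encode_shortcode()` / `decode_shortcode()`) — the whole
  annotation as one token `DNF1:<base64url payload>`, DEFLATE-compressed
  and CRC-16-protected, whose alphabet avoids `; = % ,`, whitespace and
  `>`, so it is safe inside FASTA headers and GFF3 attribute columns.
- **Carriers** (`annotate_fasta()`, `annotate_gff()`, `extract_fasta()`,
  `extract_gff()`, `convert()`) — embed and recover the token without
  disturbing a single other byte of the carrier file.
- **Comparator** (`compare_annotations()`, `render_report()`) — a
  leaf-by-leaf diff of two studies with similarities/differences views.
- **Questionnaire** (`build_questionnaire()`, `answer_current()`,
  `go_back()`, `finalize()`) — a branching, revisable interview that can
  only ever produce valid annotations; the CLI drives it interactively or
  from an answers file.
- **CLI** (`run_denofo()`, script at `inst/scripts/denofo`) — `validate`,
  `convert`, `compare`, `extract`, `questionnaire`, `version` subcommands.

## Worked example

```r
library(denofor)

ann <- denofo_annotation(
  input_data = dnf_input_data(c("transcriptome_assembly", "ribosome_profiling"),
                              minimum_orf_length_codons = 30L),
  evolutionary_information = dnf_evolutionary_information("phylostratigraphy",
                                                          outgroup_count = 6L),
  homology_filter = dnf_homology_filter(
    dnf_tool("blast", database = "nr 2024-01", evalue_threshold = 1e-5),
    "no_hit_in_any_outgroup"))

cat(write_dngf(ann))
```

```
{
  "format_version": "1.0",
  "input_data": {
    "candidate_sources": [
      {
        "kind": "predefined",
        "vocabulary": "candidate_sources",
        "term": "ribosome_profiling"
      },
      ...
    ],
    "minimum_orf_length_codons": 30
  },
  ...
}
```

The same record as a carrier-safe token (61 characters here):

```r
encode_shortcode(ann)
#> [1] "DNF1:AAMxLjAAAgACAAECHgAAAQYBAAADCm5yIDIwMjQtMDEFMWUtMDUAAMSb"
```

Comparing against a second study that used synteny-based age inference:

```r
b <- ann
b$evolutionary_information$age_inference <-
  dnf_predefined("age_inference", "synteny_based")
cat(render_report(compare_annotations(ann, b), "differences"))
```

```
DeNoFo comparison report (differences)
format versions: 1.0 vs 1.0

[evolutionary_information]
  age_inference: phylostratigraphy  <>  synteny_based

counts: equal=12 differing=1 only_in_first=0 only_in_second=0
```

The counts line reads: of the 13 schema leaves, 12 are annotated
identically in the two studies and exactly one differs — the age-inference
method.

From a shell, the same operations run through the CLI:

```sh
denofo validate study.dngf
denofo convert --from dngf --to fasta --in study.dngf --carrier genes.fasta --out genes.annotated.fasta
denofo compare study_a.dngf genes.annotated.fasta --mode differences
```

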