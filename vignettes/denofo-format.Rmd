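---
title: "The DeNoFo methodology annotation format: model, codecs and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The DeNoFo methodology annotation format: model, codecs and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denofor)
```

## The problem the format addresses

Studies of *de novo* gene emergence disagree not because one is wrong but
because they make different methodological commitments: where candidate
ORFs come from, how gene age is dated, what "no detectable homolog" means
operationally, whether the ancestral non-genic state must be demonstrated
by a non-coding homolog in outgroups, and what experimental evidence is
accepted for transcription and translation. The DeNoFo record captures all
of these in one document per study. It is deliberately *not* per-gene: a
methodology applies uniformly to every gene a study reports, so a single
record covers the whole dataset and two records make two studies
comparable.

## The data model

The root record carries a `format_version` and exactly six section slots,
in fixed order: `input_data`, `evolutionary_information`,
`homology_filter`, `non_coding_homologs`, `lab_verification`,
`hyperlinks`. The first three are mandatory — a *de novo* call cannot be
interpreted without knowing the candidate source, the age inference and
the homology filter — while the last three describe supplementary
evidence and may be absent. Which sections to mark mandatory was a design
decision of this package; the split follows what is indispensable to
interpret any *de novo* call versus what strengthens it.

Most fields are `dnf_choice` values: either a term from a controlled
vocabulary or custom free text. The vocabularies ship as a JSON registry
(`inst/extdata/vocabularies-1.0.json`) keyed by vocabulary id, so future
format versions can add terms without code changes. Term order in the
registry is frozen per format version because the shortcode serializes
predefined terms as indices into that order. The specific term lists
declared here (five candidate sources, three age-inference approaches, six
homology tools, and so on) are this package's version-1.0 registry, chosen
to cover the common methodological repertoire of the field; anything not
listed is expressible as a custom answer, which is always carried
byte-for-byte (any Unicode, including `;`, `=`, `%`, newlines) apart from
trimming surrounding whitespace.

Two rules deserve explanation:

* `non_coding_homologs`: if a study *required* a detectable non-coding
  homologous region to classify a gene as *de novo*
  (`required_for_classification = TRUE`), it must state at least one
  detection method — the requirement is meaningless without an operational
  procedure.
* evidence lists in `lab_verification` may state `none`, but `none` may
  not co-occur with actual evidence terms in the same list.

`validate_annotation()` checks every rule and reports *all* violations
with field paths, never just the first, and never throws: the result is a
value, so user interfaces and pipelines can render it as they wish.

## Canonical form

Every codec serializes the canonical form produced by `canonicalize()`:
custom text trimmed, every choice list ordered (predefined terms first,
sorted bytewise by term id; custom answers after, sorted bytewise by
text), homology searches ordered by their canonical field rendering, links
ordered by kind then value, counts stored as integers. Sorting uses
C-locale byte order (`order(method = "radix")` on UTF-8-marked keys) so
the order — and therefore every serialized byte — is identical across
platforms and locales. Canonicalization is idempotent, and equality of
methodologies is defined as `identical()` on canonical forms. The
shortcode's injectivity guarantee ("one canonical annotation, one token")
is only possible because a unique normal form exists; that is why searches
are sorted too, although they are not choice lists.

## The .dngf document dialect

`.dngf` files are strict JSON: one top-level object, keys in fixed order
(`format_version`, then the six sections), two-space indentation, UTF-8
without BOM, `\n` newlines, trailing newline, absent optional sections
omitted rather than written as `null`. The fixed layout makes a line diff
of two `.dngf` files meaningful. Reading is lenient where writing is
strict: unknown top-level keys are ignored with a warning, and a
predefined term unknown to this build's registry — as happens when a
document was written under a newer minor format version — is preserved as
a custom value carrying the original term id, with a warning, never
dropped. A newer *major* version is refused outright with an error naming
both versions. Numbers are written at full precision
(`jsonlite::toJSON(digits = NA)`), so thresholds round-trip exactly.
Syntax errors are reported with an approximate line and column recovered
from the JSON parser's error context.

## The shortcode wire format

A shortcode is `DNF<codec digit>:<payload>`. The codec digit is
independent of the schema's `format_version` (which travels inside the
payload): carriers can be scanned with one pattern while both the codec
and the schema evolve separately. The payload is built as:

1. a canonical byte serialization — format version as a length-prefixed
   UTF-8 string; one presence bitmask for the optional sections; fields in
   schema order; predefined terms as unsigned LEB128 varints indexing the
   frozen vocabulary order; custom strings as length-prefixed UTF-8;
   counts as varints; booleans as single bytes;
2. thresholds as length-prefixed *decimal strings* (shortest of `%.15g` /
   `%.17g` that reproduces the IEEE double exactly) — exactness and
   cross-platform stability were preferred over packing float bit
   patterns;
3. DEFLATE compression, applied only when it shortens the stream (one
   leading flag byte records which branch was taken);
4. a CRC-16/CCITT-FALSE checksum over flag byte plus body;
5. base64url encoding (`-`/`_` alphabet, no padding).

The resulting alphabet `A–Z a–z 0–9 - _ :` contains none of the
characters that are structural in FASTA headers (`>`, whitespace) or GFF3
attributes (`;`, `=`, `%`, `,`), so tokens embed without escaping.
Decoding verifies, in order: prefix and codec version, alphabet, canonical
base64 (the final character's unused bits must be zero — otherwise a
mutation there could decode to the same bytes and slip past the checksum),
checksum, decompression, structural parse with bounds checks, and full
schema validation. Any failure is an integrity error; a corrupted token is
never decoded into a silently wrong annotation. A 16-bit checksum admits a
false-accept probability of about 2⁻¹⁶ per corruption, which at the test
scale of 500 corruptions amounts to an expected ≈0.008 undetected cases;
the canonical-encoding check removes the one systematic class of
collisions (final-character trailing bits).

Annotations whose content is entirely vocabulary-indexed (no custom text,
no free-text databases or links) encode to about 60–110 characters,
comfortably inside a header line.

## Carriers: FASTA and GFF3

The embedding contract is byte preservation: removing the token from an
annotated file must reproduce the input exactly. For that reason the
carrier code edits files at the line level — re-serializing through a
sequence-object library would re-wrap sequences and reorder attributes.
The standard parsers (`Biostrings`, `rtracklayer`) are instead used in the
test suite as independent oracles that the annotated output still parses.
In FASTA the token is appended as the last whitespace-delimited word of
the header (`denofo=DNF1:...`), keyed by the first word of the header; in
GFF3 it is a lowercase `denofo` attribute appended to column 9 with a
single `;` (lowercase because GFF3 reserves uppercase-initial attribute
keys), keyed by the `ID` attribute with `<seqid>:<start>-<end>` as
fallback (coordinates verbatim, 1-based inclusive, no arithmetic).
Re-annotation replaces an existing token, so a record never carries two.

One annotation per file is the expected case. Extraction still reads
per-record tokens, but converting a carrier back to `.dngf` requires all
embedded annotations to agree and otherwise fails with a conflict error
listing the differing record ids — a mixed file is a real inconsistency
the user must resolve, not something to silently collapse.

## The comparator

Reports are at leaf-field granularity (13 leaves across the six sections),
grouped by section, because the typical question is "identical except
which fields?". Both inputs are canonicalized first, so list order and
whitespace can never masquerade as differences, and list-valued fields
compare as sets of canonical values. A custom answer never equals a
predefined term even when the text coincides with the term's label — free
text and a controlled term are different epistemic claims, so the pair is
reported as differing with both renderings shown. Optional sections
present in only one study are reported as `only_in_first`/`only_in_second`
per leaf; a leaf absent from both studies counts as `equal` (rendered
"(absent)") so that the four counts always partition the full leaf set.
`format_version` is not a diff entry; a major-version mismatch instead
raises a prominent warning in the report header while the comparison
proceeds. The similarities and differences render modes partition the
entries, and both end with the same counts line.

## The questionnaire

The engine is a pure state machine — state in, state out, no terminal I/O —
so the CLI readline loop and the non-interactive `--answers` file driver
are equally thin, and the whole path is testable without a TTY. Questions
follow section order; each optional section opens with one boolean gate
question, keeping the mandatory path short while the optional sections
remain reachable. Branch predicates are functions of earlier answers: the
detection-methods question, for instance, is applicable only when the
non-coding-homolog section is included *and* the homolog was required for
classification. Changing a gate answer after `go_back()` discards the
answers that became unreachable, so the answer map can never contain
orphans. `finalize()` either returns a canonical annotation that passes
validation or fails with a completeness error naming every unanswered
required question; it has no third outcome.

One deliberate simplification: the homology-search question collects the
set of tools used (each becoming a `ToolInvocation` without thresholds);
per-search databases and thresholds are edited programmatically or in the
`.dngf` file rather than through per-tool sub-dialogues, which would
triple the questionnaire's length for its rarest inputs.

## The fixture generator

`generate_annotation()` draws random valid annotations under an explicit
seed, with three dials: `p_custom = 0.3` (the probability a choice field
is a custom answer — high enough that every codec path sees free text
constantly), `p_optional = 0.5` (presence of each optional section and
field), and `adversarial_text`, which draws custom answers from a pool of
codec-hostile strings: `;`, `=`, `%`, `,`, tabs, newlines, emoji, CJK
text, kilobyte-long strings, and FASTA/GFF look-alikes such as
`>fake_header` and `key=value%20encoded`. Every generator saves and
restores the caller's RNG state, so fixtures are pure functions of their
arguments. The toy FASTA/GFF generators produce structurally correct
carriers (wrapped 60-column sequences; 9-column features with unique IDs
and ordered coordinates) with no biological realism — they exercise the
format, not gene biology. Consequently the passing test suite demonstrates
format correctness (round trips, byte preservation, corruption detection,
diff exactness) on well-formed carriers; it says nothing about, e.g.,
tolerating FASTA dialects with non-standard headers or GFF2/GTF files,
which are out of scope.

## Problem sizes and numerical choices

The test suite and the acceptance script use 1,000 seeded fixtures for the
document and shortcode round trips, 500 single-character token
corruptions, 200 questionnaire fuzz runs, 1–5 injected edits for the
comparator, and 50-record carrier checks; unit tests run reduced versions
of the same properties (100–150 fixtures) for fast iteration. All
randomness flows from explicit integer seeds. Ties in canonical sorting
cannot occur between distinct values because sort keys embed a `\x01`
separator and kind discriminator; duplicate predefined terms are validation
errors, and duplicate custom answers sort stably by text.

## Known limitations

* Interoperability with files written by other DeNoFo implementations is
  not claimed: key names and vocabulary wording here are this package's
  own declarations.
* The shortcode registry freezes term order per format version; editing
  the registry file in place (rather than adding a new version) would
  silently re-map existing tokens. Registry edits must therefore only
  append, or bump the format version.
* Carrier parsing is deliberately minimal (line-level); pathological FASTA
  with `>` inside descriptions of wrapped headers, or GFF3 with escaped
  `;` inside the `ID` value, are outside the supported grammar.
* The comparator reports structure, not semantics: two studies using
  different tools with equivalent sensitivity are still "different".
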