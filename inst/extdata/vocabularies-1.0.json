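{
  "format_version": "1.0",
  "vocabularies": {
    "candidate_sources": [
      "genome_annotation",
      "transcriptome_assembly",
      "ribosome_profiling",
      "mass_spectrometry",
      "six_frame_orf_scan"
    ],
    "orf_definition": [
      "start_to_stop",
      "longest_orf_per_transcript",
      "annotated_cds"
    ],
    "age_inference": [
      "phylostratigraphy",
      "synteny_based",
      "gene_tree_reconciliation"
    ],
    "phylogeny_source": [
      "published_tree",
      "inferred_in_study",
      "taxonomy_database"
    ],
    "homology_tools": [
      "blast",
      "diamond",
      "hmmer",
      "jackhmmer",
      "mmseqs2",
      "exonerate"
    ],
    "homology_criterion": [
      "no_hit_in_any_outgroup",
      "no_hit_beyond_focal_clade"
    ],
    "noncoding_detection": [
      "synteny_alignment",
      "whole_genome_alignment",
      "local_alignment"
    ],
    "transcription_evidence": [
      "rnaseq",
      "est",
      "rt_pcr",
      "cage",
      "none"
    ],
    "translation_evidence": [
      "riboseq",
      "mass_spectrometry",
      "western_blot",
      "reporter_assay",
      "none"
    ]
  }
}
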