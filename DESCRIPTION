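Package: immunodnds
Title: Immune dN/dS Estimation Inside and Outside the Immunopeptidome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates somatic selection on antigenic mutations by comparing
    trinucleotide-context-corrected dN/dS inside (ON-target) and outside
    (OFF-target) an MHC class I immunopeptidome. Provides readers for
    annotated mutation tables, transcript-coordinate BED regions, CDS FASTA
    and precomputed MHC-binder tables; a 192-class trinucleotide substitution
    model for context-weighted site counting; cohort- and patient-level
    immune dN/dS with confidence intervals, intronic background correction,
    driver exclusion and target randomization; immunopeptidome construction
    from binder tables with binding-rank, positive-assay and expression
    filters; downstream interpretation (edited-neoantigen counts, immune
    selection categories, escape classification); a branching-process tumor
    simulator with immune attack; and a synthetic-fixture generator with
    known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
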