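Package: opsinevol
Title: Molecular Evolution of Visual Opsin Genes: Pseudogene Lesions,
    Spectral Tuning, Codon-Model Selection Tests, and Loss Dating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the molecular evolution of vertebrate visual
    opsin coding sequences on a phylogeny. Detects open-reading-frame lesions
    (frameshift indels, premature stop codons, splice-boundary violations) and
    classifies sequences as functional or pseudogenised; infers spectral
    sensitivity (lambda-max) from key amino-acid tuning residues in bovine
    rhodopsin numbering (the LWS five-site rule and SWS1 UV/violet sites);
    estimates dN/dS under Goldman-Yang codon substitution models with one-ratio,
    two-ratio, free-ratio and site-mixture (M1a/M2a/M7/M8) parameterisations and
    likelihood-ratio tests; reconstructs ancestral amino-acid states by Fitch
    parsimony and marginal maximum likelihood and classifies convergent versus
    divergent substitutions between lineages; dates loss of selective constraint
    on pseudogenised lineages under a sudden-relaxation model; and simulates
    codon alignments with branch-specific dN/dS and injected loss-of-function
    lesions so every stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite,
    Matrix
Config/testthat/edition: 3
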