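Package: indelmsa
Title: Multiple Protein Sequence Alignment with Indel-Flanking-Region
    Aware Variable Gap Penalties
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Progressive multiple protein sequence alignment in which the
    gap penalty varies along each sequence. Two variable-order Markov
    models (prediction by partial match, PPM) trained on the left and
    right flanking regions of indels score every length-10 window of an
    input sequence by its average log-loss; the position-specific gap
    opening penalty is the smaller of the two log-loss profiles and the
    gap extension penalty drops to zero inside predicted indel flanking
    regions (IndelFRs). Sequences are aligned progressively along a UPGMA
    guide tree built from approximate-matching pairwise distances, using
    three-state affine dynamic programming with the variable penalties,
    optionally in linear space. Includes sum-of-pairs and total-column
    scoring against reference alignments with core blocks, a synthetic
    protein-family simulator with known true alignments and indel sites,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
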