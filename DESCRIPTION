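Package: alphscreen
Title: Proteome-Wide Identification of ApaH-Like Phosphatases by Motif-Matrix Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies ApaH-like phosphatases (ALPHs) in proteome FASTA files by
    scanning for six conserved sequence motifs modelled as position-specific
    allowed-residue sets (narrow and extended flavours), assembled under
    inter-motif spacing constraints with a budget of at most two extended-matrix
    motifs per protein. Provides domain annotation (N-terminus, catalytic
    domain, C-terminus), catalytic-domain extraction, one-motif-missing and
    truncated-protein audit screens, corpus-level summary statistics
    (inter-motif distance distributions, isoform counts, motif count matrices
    for sequence logos), a labelled synthetic-proteome generator for testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
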