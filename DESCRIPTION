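Package: mitoduplex
Title: Duplex-Sequencing Simulation and Ultra-Rare Mitochondrial Mutation Analysis
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying germline mitochondrial DNA mutagenesis in
    mutation-accumulation (MA) line experiments. Simulates heteroplasmy drift
    through a single-individual germline bottleneck, generates UMI-tagged
    duplex read families with realistic sequencing/PCR/end-artifact error
    strata, forms single-strand and duplex consensus sequences with the
    standard Duplex-Seq filters (minimum family size, consensus fraction,
    end clipping), calls ultra-rare single nucleotide mutations, and computes
    mutation frequencies, six-class spectra, strand asymmetry, 96-context
    trinucleotide signatures, spectrum-aware dN/dS under the invertebrate
    mitochondrial genetic code, and the cross-group statistics used in
    MA-line studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
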