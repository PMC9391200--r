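Package: pepcleft
Title: Charge-Interaction Analysis of HLA Class I Immunopeptidomes
Version: 0.1.0
Authors@R: person("Repertoire", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing charge-based interactions between HLA class I
    binding-cleft residues and eluted peptide ligands. Provides quality-control
    filtering and deduplication of mass-spectrometry peptide tables, dual-end
    positional frequency matrices, residue-class enrichment (acidic position 4,
    basic position 1), wild-type versus mutant motif-change quantification,
    Kullback-Leibler sequence logos and motif-based allotype assignment,
    position-pair co-occurrence statistics, grouping of allotypes by
    binding-cleft residue configurations, and geometric/electrostatic contact
    analysis (salt bridges, hydrogen bonds, pi interactions, coulombic pair
    energies, Kabsch superposition and RMSD) of HLA-peptide structure
    ensembles. A synthetic-data module generates peptide repertoires and
    coordinate ensembles with known ground truth so that every stage of the
    pipeline is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
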