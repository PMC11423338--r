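Package: ievgen
Title: Conditional Molecule Generation from Protein-Ligand Interaction
    Energy Vectors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-residue interaction energy vectors (IEVs) that
    quantify the van der Waals, Coulomb and hydrogen-bond energies between
    a docked ligand pose and the residues of a protein binding pocket, and
    couples them to a conditional molecular generator: a variational
    autoencoder over SMILES strings, a second variational autoencoder over
    IEVs, and a fusion network that maps the joint latent space back into
    the SMILES latent space so that molecules can be sampled conditioned
    on a target interaction profile. Includes dataset preparation
    (canonicalization, largest-component retention, deduplication,
    fingerprint-based cluster splitting), the standard generative-model
    evaluation metrics (validity, uniqueness, internal diversity,
    interaction-retention counts), and a fully synthetic fixture generator
    (toy pockets, deterministic ligand poses, paired SMILES/IEV datasets)
    so the whole pipeline runs without external docking software.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    bio3d,
    ChemmineOB
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
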