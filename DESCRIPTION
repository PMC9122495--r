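Package: droplens
Title: Coarse-Grained Modelling and Analysis of Seipin-Mediated Lipid Droplet Biogenesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study triacylglycerol (TG) nucleation and lipid droplet
    (LD) formation at the seipin cage. Provides reduced-resolution grouping of
    atomistic membrane simulations, a switching-function coordination statistic
    for protein-lipid contacts, position-dependent lateral diffusion analysis,
    a highly coarse-grained (CG) builder for the 11-subunit seipin complex
    (4 residues per bead, elastic networks, heterogeneous fluctuation-matched
    springs, attraction scaling factors), a desk-scale Langevin dynamics engine
    with LAMMPS export, oil-lens morphology metrics (nucleation percentage,
    shape anisotropy, ER-LD neck diameter, RMSF), and synthetic-data
    generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
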