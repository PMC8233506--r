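Package: epistasim
Title: Historical Contingency in Experimental Evolution: Simulation and
    Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for asking whether a recurrent beneficial
    mutation that fails to substitute in replicate evolving populations does so
    by chance or by historical contingency (epistasis). Provides an
    individual-based Wright-Fisher simulator of a focal allele arising by
    recurrent mutation amid competing background mutations with a configurable
    distribution of fitness effects; Luria-Delbruck fluctuation-test mutation
    rate estimation via the Ma-Sandri-Sarkar maximum-likelihood recursion with
    plating-efficiency correction; serial-transfer competition fitness
    calculus; Baranyi-Roberts growth-curve fitting and double-strain virtual
    competitions over a shared nutrient pool; Dice mutation-set similarity with
    label-permutation nulls; and exact binomial, Wilson-interval and Fisher
    contingency statistics built on explicit enumeration. A synthetic-data
    module generates every laboratory-shaped input (plate-reader optical
    density series, fluctuation-assay colony counts, competition plate counts,
    clone-by-gene mutation tables) so the full analysis is reproducible without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
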