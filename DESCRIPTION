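Package: eggmorph
Title: Coevolutionary Dynamics of Egg-Phenotype Polymorphism in Avian
    Brood Parasitism
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Deterministic, discrete-time frequency dynamics of a
    maternally inherited, two-trait egg phenotype (background color
    white/blue crossed with immaculate/spotted) in a coevolving
    host-parasite pair, motivated by cuckoo brood parasitism on small
    passerines.  Hosts reject foreign eggs with a probability that
    grows with phenotypic mismatch; parasitism is random at a fixed
    rate; both traits mutate reciprocally.  The package iterates the
    coupled selection-mutation recursion, classifies the dynamical
    regime (stable coexistence, sustained oscillation, heteroclinic-like
    cycling), linearizes the map at its equilibria to obtain eigenvalue
    stability reports, locates critical mutation probabilities by
    bisection on the spectral radius, checks the inverse-square-root
    scaling of the oscillation period with the parasitism rate, and
    ships named scenario presets with CSV/JSON writers and a small
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
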