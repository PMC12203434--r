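Package: adld
Title: Atomic Decomposition of London Dispersion Energy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Partitions semiclassical London dispersion energies into atomic
    and fragment contributions. Provides two pairwise dispersion engines (a
    classic London-formula model and a coordination-number-dependent C6/C8
    model with Becke-Johnson damping), a pluggable charge-scaling layer,
    intra/intermolecular splitting of dimer dispersion energies, Gaussian
    smeared dispersion-density scalar fields written as Gaussian cube files,
    and mass-scaling regression diagnostics (the gravitational-like M1*M2/R
    law and its generalized M1^2+M2^2 form). Includes deterministic synthetic
    geometry generators, XYZ and delimited-table interchange I/O, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
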