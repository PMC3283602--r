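Package: g4char
Title: Biophysical Characterization of G-Quadruplex DNA and Its Ligand Complexes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the in-vitro characterization workflow of promoter
    G-quadruplex (G4) DNA: scanning sequences for putative G4 motifs,
    assigning native electrospray mass-spectrometry peaks of DNA-ammonium-ligand
    complex ions and computing the relative binding-affinity intensity ratio
    (IRa), classifying G4 topology from circular-dichroism band positions,
    and fitting two-state van't Hoff thermodynamics to thermal melting curves
    to quantify ligand-induced stabilization (delta-Tm, delta-delta-H,
    delta-delta-G). Includes seeded generators for synthetic mass spectra,
    CD spectra and melting curves so every stage can be exercised and
    validated by parameter recovery without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
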