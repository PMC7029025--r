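Package: lipoladder
Title: Homolog-Ladder Annotation of Cyclic Lipopeptide Isoform Families from LC-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates families of lipopeptide isoforms from LC-MS peak lists:
    detects CH2 homolog ladders (14.016 Da spacing) and water-related
    cyclic/linear partners (18.011 Da), infers beta-hydroxy fatty-acid tail
    lengths from an anchored member, assigns alphabetical designations, and
    verifies candidate structures against MS2 fragment spectra including the
    +18 Da ring-opening daughter-ion topology test. Includes exact
    monoisotopic elemental-formula arithmetic, a structure-activity module
    relating tail length to antimicrobial potency, and a synthetic LC-MS data
    generator with recorded ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
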