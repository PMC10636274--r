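Package: midquant
Title: Mass Isotopomer Distribution Quantification for Stable Isotope Labeling MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch extraction, integration and natural-isotope-abundance
    correction of mass isotopomer distributions (MIDs) from targeted stable
    isotope labeling mass spectrometry experiments. Reads mzML, mzXML and
    ANDI-MS netCDF runs, extracts per-isotopologue ion chromatograms, locates
    chromatographic peaks on composite (summed-isotopologue) traces so that a
    single set of integration bounds is shared by every isotopologue of a
    cluster, computes MIDs and average percent enrichments, and corrects them
    for natural isotopic background from the molecular formula of each ion.
    Supports low- and high-resolution instruments, MS and MS/MS acquisition,
    and single- or dual-isotope tracers (2H, 13C, 15N, 18O, 34S), plus a
    ground-truth synthetic-run generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mzR,
    signal,
    pracma,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
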