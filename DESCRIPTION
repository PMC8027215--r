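Package: sipbands
Title: Stable Isotope Probing Gradient Simulation, Label Classification
    and Carbon Atom Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nucleic-acid stable isotope probing (SIP) in
    isopycnic density gradients. Simulates CsCl (DNA) and CsTFA (RNA)
    gradient fraction tables for synthetic communities with defined GC
    content and 13C atom fractions; reads, writes, pools and total-sum
    scales OTU-by-fraction tables; classifies OTUs as unlabelled,
    partially or strongly 13C-labelled using threshold criteria on
    relative-abundance shifts between light and heavy fractions together
    with standard-gradient density calibration; and traces carbon atoms
    through nucleic-acid synthesis pathways to predict ribose 13C atom
    fractions and expected band positions under mixotrophic, heterotrophic
    and autotrophic labelling scenarios, with delta-13C mass-balance
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
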