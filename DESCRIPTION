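Package: lipidsip
Title: Lipid Stable-Isotope-Probing Rate and Turnover Estimation for AOM Incubations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Infers methane-oxidation rates, compound-specific carbon-assimilation
    rates and lipid turnover times from 13C stable-isotope-probing (SIP)
    incubations of anaerobic methane-oxidising (AOM) sediment communities.
    Provides delta-13C / atom-fraction conversions against VPDB, correction of
    derivatization carbon in FAME and TMS measurements, bulk geochemical rate
    estimators for sulphate, sulphide and dissolved inorganic carbon, label-transfer
    methane-oxidation rates, lipid-specific inorganic-carbon and methane-carbon
    assimilation estimators with turnover times, and a seeded forward simulator of
    the four-treatment SIP design (labelled and unlabelled DIC and CH4 with killed
    controls) for validation and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
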