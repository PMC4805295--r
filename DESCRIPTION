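Package: mangrovehydro
Title: Hydrological Classification of Tidal Wetland Sites for Mangrove
    Restoration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn raw water-level logger series from intertidal
    sites into hydrological suitability assessments for mangrove
    restoration. Reads and barometrically compensates 5-minute pressure
    logger records, estimates the soil surface level from the slope break
    (nod point) on ebb recession limbs, extracts inundation events under a
    15-minute minimum-duration rule, computes duration-of-inundation
    statistics, assigns sites to an ordinal hydrological class scale
    (1, 2, 2*, 3, 4, 5), maps vegetation inventories to expected classes
    via a packaged species catalogue, estimates site elevation relative to
    mean sea level by high-tide overlay on an open-water series, diagnoses
    flow obstruction (tailing, capping) against a counterfactual
    free-exchange inundation regime, and emits per-site management advice.
    A synthetic tide and site-response simulator with known ground truth
    supports testing and worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
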