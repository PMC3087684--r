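Package: BrachioGS
Title: Genome-Size Evolution in the Brachionus plicatilis Cryptic Species Complex
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of haploid genome-size (C-value) evolution in
    the rotifer Brachionus plicatilis cryptic species complex. Implements
    internal-standard flow-cytometry genome-size estimation from fluorescence
    histograms, picogram/megabase conversion, clone and species aggregation,
    whole-genome-duplication (ploidy-multiple) inference, nested REML variance
    components across taxonomic levels, Felsenstein's phylogenetically
    independent contrasts with through-origin correlation, Abouheif's test for
    serial independence with rotation averaging and a permutation null, ellipsoid
    body/egg volume morphometrics, and seedable synthetic-data generators
    (Brownian-motion traits on trees, nested random-effects designs, Gaussian
    fluorescence peaks) that emulate every statistical structure the analysis
    assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
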