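Package: tractfa
Title: Tract-Specific Analysis of White-Matter Fractional Anisotropy
Version: 0.1.0
Authors@R:
    person("R.", "Walsh", email = "rwalsh@example.org", role = c("aut", "cre"))
Description: Tools for tract-specific analysis (TSA) of diffusion-tensor
    fractional anisotropy (FA) on medial skeleton models of white-matter
    tracts. Builds discrete medial models (skeleton surface plus spokes)
    from binary tract volumes, projects maximum FA along spokes onto the
    skeleton surface, and performs pointwise group contrasts and
    score regressions with non-parametric cluster-based permutation
    inference and familywise-error correction. Includes a synthetic-data
    module generating tract phantoms and patient/control cohorts with
    localized FA lesions and FA-score couplings, neuropsychological
    scoring and summary-statistic group comparisons, NIfTI-1 and VTK
    legacy polydata input/output, and a command-line interface chaining
    the stages.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
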