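Package: dcespect
Title: Voxel-Wise Correlation of DCE-MRI Perfusion Parameters with SPECT
    Radiopeptide Uptake
Version: 0.1.0
Authors@R: person("dcespect", "maintainers", email = "dcespect@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline linking dynamic contrast-enhanced MRI
    perfusion and permeability parameters to radiolabeled-peptide uptake
    imaged by SPECT in somatostatin-receptor-positive tumors.  Provides
    variable-TR T1 relaxometry and SPGR signal-to-concentration conversion,
    six semi-quantitative enhancement-curve features with per-dataset
    min-max normalization, standard Tofts pharmacokinetic modelling with a
    bi-exponential arterial input function and a low-enhancement zeroing
    gate, mask-based rigid + affine registration between the MRI and SPECT
    frames, and voxel-wise spatial statistics (Spearman rank correlation,
    bidirectional decile summaries, pooled decile regression).  A synthetic
    phantom with a receptor-saturation uptake model stands in for in-vivo
    data, so the whole pipeline is testable end to end.  Includes minimal
    NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
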