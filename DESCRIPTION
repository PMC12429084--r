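Package: alpsim
Title: Synthetic Diffusion MRI Phantoms, DTI-ALPS Computation, and Bootstrap
    Mediation for Perivascular-Space Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study glymphatic function in silent cerebral small
    vessel disease with the diffusion tensor image analysis along the
    perivascular space (DTI-ALPS) index. Provides a synthetic-data layer
    (diffusion-weighted phantoms with prescribed axis diffusivities and
    Rician noise, and cohort tables with configurable enlarged
    perivascular space prevalence, group means and structural mediation
    paths), log-linear diffusion tensor fitting, ROI-based ALPS index
    computation, semi-quantitative ePVS grading and rater agreement,
    the cohort statistical battery (t, Mann-Whitney, chi-square, Fisher,
    Pearson, logistic and linear models, variance inflation factors),
    and simple mediation with bias-corrected bootstrap confidence
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
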