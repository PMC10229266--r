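Package: lvshape
Title: Statistical Shape Modelling of Left Ventricular Remodelling in
    Hypertrophic Cardiomyopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study left ventricular (LV) remodelling associated with
    outflow tract obstruction in hypertrophic cardiomyopathy from corresponded
    surface meshes. Provides a parametric synthetic LV cohort generator
    (basal septal hypertrophy, apical dilatation, LV lengthening and outflow
    tract inward remodelling, with Bernoulli pressure-drop and genotype
    labels), template-mesh personalization to short-axis binary segmentations,
    nodal wall thickness with AHA 17-segment aggregation, a PCA statistical
    shape model (point-distribution model), Fisher linear discriminant
    remodelling axes quantified as Z-scores with extreme-shape synthesis, and
    ROC/leave-one-out validation, orchestrated by a reproducible study
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    mgcv,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
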