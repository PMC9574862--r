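Package: protacsol
Title: Physicochemical Profiling and Solubility Classification of PROTACs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis toolkit for profiling the developability of
    proteolysis-targeting chimeras (PROTACs) from experimental and computed
    physicochemical data. Converts raw chromatographic retention times into
    the lipophilicity descriptors BRlogD and log kw(IAM) and the polarity
    descriptor delta log kw(IAM); quantifies thermodynamic shake-flask
    solubility from HPLC-UV calibration curves with censoring below the
    quantification limit and assigns GSK solubility classes; computes the
    2D descriptors nC, Ertl topological polar surface area and Kier's
    flexibility index from structures; evaluates conformer-ensemble 3D polar
    surface area with Tukey adjacent-limit summaries; and fits the
    descriptor-solubility regressions and the BRlogD/TPSA decision-tree
    solubility classifier, with stratified cross-validation. A synthetic-data
    generator reproduces the statistical structure of the measured dataset so
    that every stage of the workflow is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    bio3d,
    jsonlite,
    yaml,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
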