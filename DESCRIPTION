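Package: mlsize
Title: Sample-Size Adequacy Evaluation for Two-Class Machine-Learning Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Evaluates whether a decided sample size is adequate for a
    two-class machine-learning study. Computes per-variable Cohen's d together
    with the average and grand aggregate effect sizes, runs a repeated
    balanced-subsampling protocol with stratified ten-fold cross-validation
    over five classifier families (support-vector machine, L2 logistic
    regression, decision tree, neural network, naive Bayes), and applies two
    decision criteria (at least one aggregate effect size at or above 0.5;
    best accuracy at or above 80 percent with between-size change below 10
    percent) plus a three-way remediation recommendation. A built-in simulator
    generates two-class Gaussian datasets with controlled per-variable effect
    sizes and a data-quality substitution manipulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    e1071,
    glmnet,
    rpart,
    nnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
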