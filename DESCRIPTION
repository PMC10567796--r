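Package: pamnet
Title: Position-Aware Motif Kernel Networks for Biological Sequences
Version: 0.1.0
Authors@R:
    person("pamnet", "developers", email = "pamnet@example.org", role = c("aut", "cre"))
Description: Interpretable neural networks for DNA and protein sequence
    classification built on a position-aware motif kernel. The first layer of
    the network performs a Nystroem projection onto a finite-dimensional
    subspace of the kernel's reproducing kernel Hilbert space, spanned by
    learnable motif-position anchor points; linear fully-connected layers on
    top keep the model directly interpretable. Includes the kernel primitives,
    the Nystroem kernel layer, end-to-end training with constrained anchor
    updates, evaluation metrics and a stratified cross-validation harness,
    global interpretation (position importance and class mean motifs) and
    local per-input explanations via motif-function norms, and a synthetic
    data generator that plants degenerate motifs at jittered positions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
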