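Package: probmotif
Title: Probabilistic Indel-Free Motif Discovery and Proteome Scanning for
    Protein Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a fixed-length position-specific probability matrix for a
    protein domain from a reference sequence set by Gibbs sampling (with greedy
    and randomized alternatives), using a +1 pseudocount occurrence model with
    no insertion or deletion states. The trained matrix is applied to whole
    proteomes by scoring every protein's profile-most-probable k-mer with a
    product-of-columns likelihood, ranking proteins by that likelihood, and
    calling candidate domain-containing proteins with two outlier criteria
    (Q3 + 3*IQR of the log10 likelihood distribution, and the 5th percentile of
    the likelihoods the matrix assigns to its own reference family). A
    column-scrambling negative control estimates the false-positive rate, and a
    synthetic planted-motif generator provides ground-truth benchmarks.
    Developed around histidine phosphotransfer (HPt) domains but applicable to
    any short, indel-free domain signature.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
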