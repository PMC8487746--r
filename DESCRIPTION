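Package: repnet
Title: Reputation, Cooperation and Payoff Inequality in Dynamic Network Games
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Agent-based simulation of repeated N-person Prisoner's Dilemma
    games on interaction networks that are either randomly rewired every
    period or strategically updated by dropping defecting partners and
    forming new links by mutual consent under a degree cap. Populations mix
    persistent altruists, persistent defectors and conditional cooperators
    whose decisions respond to reputational information (average executed
    action over a sliding window). Provides the two group-level inequality
    outcomes -- the Gini coefficient of accumulated payoffs (dispersion) and
    the Pearson correlation between cooperation rate and final payoff
    (correspondence) -- replicated parameter sweeps over population
    compositions, an exact binomial sign test and a Mann-Whitney U test for
    meta-analysis of control-treatment experiment pairs, and a synthetic
    generator of group-level experiment outcomes for testing the
    meta-analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils, graphics, Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, yaml, optparse
Config/testthat/edition: 3
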