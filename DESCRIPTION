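Package: eqaplan
Title: Planning and Auditing Participation in External Quality Assessment
    Schemes for Human Genetics Laboratories
Version: 0.1.0
Authors@R:
    person("EQA", "Planning Working Group", role = c("aut", "cre"),
           email = "eqaplan@example.org")
Description: Rule-based planning, compliance auditing and budgeting of a
    medical genetics laboratory's participation in external quality
    assessment (EQA, proficiency testing) schemes.  Implements a multi-year
    participation planner with annual technique coverage, triennial
    genotyping/interpretation coverage, volume-based triennial exemptions
    and poor-performance escalation rules; a Bayesian binomial error-rate
    model under noninformative Beta priors that derives the minimum annual
    test volume compatible with a bounded error rate; t-based confidence
    intervals for literature error-rate summaries; cost-scenario budgeting;
    and a seeded synthetic generator for scheme inventories, center
    profiles and participation histories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
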