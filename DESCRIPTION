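Package: crisischat
Title: Evaluation of Hybrid AI and Moderator Crisis Detection in Peer Support Chats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing moderated group-chat transcripts from digital
    peer support services in which an AI classifier and a human moderator
    jointly flag suicidal-ideation (SI) risk. Implements confusion-matrix
    evaluation of the AI flag against the moderator's risk-protocol benchmark,
    flag and crisis-referral latency analysis, SI prevalence summaries,
    normalized-timeline emotion trajectory analysis with propensity-score
    matching (logit-scale caliper) and ANCOVA group-by-time comparison,
    n-gram phrase frequency tables, and a calibrated synthetic transcript
    generator so that the full pipeline runs and is testable without access
    to private chat data.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
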