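Curated case-study candidate tables: published top-20 predicted circRNA
partners for four anticancer drugs (doxorubicin, gefitinib, sorafenib,
paclitaxel), each flagged 1 if the association was externally verified
against the Cancer Therapeutics Response Portal (CTRP) literature, else
0.  Read with readCaseStudyTable(); verificationRate() recomputes the
per-drug verification percentages.
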