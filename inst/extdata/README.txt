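synthetic_cough_demo.csv: a SYNTHETIC three-document demonstration corpus.
The per-point counts are invented; only a few summary facts mirror the
published frequency narrative for the cough chapters of the three classical
textbooks (DEBG: 18 distinct points with BL13 most frequent at 6; CGGHB:
31 distinct points with LI4 most frequent at 6 and BL13 at 4; SADI: 14
distinct points with SP3 most frequent at 3; LI4 absent from DEBG/SADI,
SP3 absent from DEBG/CGGHB, BL13 absent from SADI). It is NOT the study
corpus, which is available only on request from its authors.
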