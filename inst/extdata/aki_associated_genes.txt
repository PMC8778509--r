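# Genes with a prior acute-kidney-injury association (subset covering the
# study's differential proteins, as published; replace with a full export of
# an AKI gene knowledgebase to annotate other datasets). One symbol per line.
ANXA3
APOE
ITGB1
HSP90B1
GM2A
SLC27A2
PRDX1
APOA4
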