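# Biofluid-detectability annotation: genes whose protein products are
# predicted detectable in serum, plasma, or urine (secretome subset covering
# the study's differential proteins; replace with a full secretome export to
# annotate other datasets). One symbol per line.
FLNA
APOE
TLN1
FLNB
ITGB1
TPP1
TCP1
HSP90B1
GM2A
CCT8
TXNDC17
GC
CCT3
CRYZ
APOA2
UPP2
PRDX1
APOA4
CCT6A
PDXK
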