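# Nominated schizophrenia risk genes shared with the 102-gene autism list
ITSN1
DSCAM
ZMYM2
SHANK3
FAM120A
ZMYND11
KDM6B
ANK2
ASH1L
CAMTA2
NRXN1
ADCY5
PSMD11
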