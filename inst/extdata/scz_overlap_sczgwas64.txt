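# Nominated schizophrenia risk genes shared with the 64-gene SCZ GWAS list
SP4
GRIN2A
CACNA1C
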