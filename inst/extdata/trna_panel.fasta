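>tRNA-iMet synthetic 3'-terminal 18-mer
GTGGGTTCGATCCCACCA
>tRNA-Lys synthetic 3'-terminal 18-mer
CAGGGTTCGAGCCCTCCA
>tRNA-Trp synthetic 3'-terminal 18-mer
GACGGGTTCAAATCCCCA
>tRNA-Ser synthetic 3'-terminal 18-mer
TCGAATCCCGCTCGGCCA
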