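cell_line,gene,direction,sequence
3134,Per1,forward,CTTCTGGCAATGGCAAGGACTC
3134,Per1,reverse,CAGCATCATGCCATCATACACACA
3134,Tgm2,forward,TGTCACCAGGGATGAGAGACGG
3134,Tgm2,reverse,TCCAAATCACACCTCTCCAGGAG
3134,Lcn2,forward,ACCTCTCATTTCTTGCAGTTCCG
3134,Lcn2,reverse,CAGGATGGAGGTGACATTGTAGCT
3134,Actb,forward,AGTGTGACGTTGACATCCGTA
3134,Actb,reverse,GCCAGAGCAGTAATCTCCTTCT
LNCaP,NKX3.1,forward,TGACAGTGGGCTGTTTGTTC
LNCaP,NKX3.1,reverse,AAGACCCCAAGTGCCTTTCT
LNCaP,RHOU,forward,TTTCAAGGATGCTGGCTCTT
LNCaP,RHOU,reverse,GGCCTCAGCTTGTCAAATTC
LNCaP,GAPDH,forward,AAGGTGAAGGTCGGAGTCAAC
LNCaP,GAPDH,reverse,GGGGTCATTGATGGCAACAATA
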