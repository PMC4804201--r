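patch,T_recurvata,T_pohliana,T_tricholepsis,T_loliacea
EP,76,40,7,9
TP,15927,207,336,207
PP,570,159,17,72
RP,44,5,0,5
SF,52,40,4,3
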