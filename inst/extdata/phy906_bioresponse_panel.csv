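gene,signed_fold,batch_id
AKR1B10,6.8,PHY906-6
CYP1A1,405,PHY906-6
EMP2,3.2,PHY906-6
G6PC,12.3,PHY906-6
GCLC,3.4,PHY906-6
GDF15,2.2,PHY906-6
HAMP,4.9,PHY906-6
IGFBP-3,3.3,PHY906-6
PALLD,2.6,PHY906-6
PIM1,3,PHY906-6
SASH1,2.8,PHY906-6
SERTAD,2.2,PHY906-6
SLC7A11,3.2,PHY906-6
SOS1,9.4,PHY906-6
TUBA3,-2.4,PHY906-6
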