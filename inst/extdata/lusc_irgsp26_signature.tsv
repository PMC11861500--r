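# cutoff: -0.024
pair_label	coefficient
ADAMDEC1|GFPT2	-0.04506
AIM2|IL18R1	0.279912
AOAH|AOC3	-0.08013
AOAH|IL2RA	-0.04986
AOAH|SAMD9L	-0.10771
AOAH|SERPINB9	-0.10108
AOAH|SLIT2	-0.00712
CD180|TRAF3IP3	0.145911
CD37|GAS1	-0.15336
CD37|MMP19	-0.09163
CHI3L1|MEST	0.078511
CYTIP|MMP19	-0.15078
DAPP1|TAGAP	-0.17731
DOCK2|IL18R1	0.181694
EGR2|PLAC8	0.03231
EGR2|TSPAN33	0.055216
ERLIN2|SERPINB9	-0.13074
ICAM3|THEMIS	0.143621
IL10RA|MMP19	-0.10313
IL2RG|SELPLG	-0.13703
ITGAL|MMP19	-0.02076
ITGB7|MILR1	-0.21373
KLHL6|TRAF3IP3	0.359815
LSM1|TRIM22	-0.11753
NCF1|P2RY8	-0.06368
REEP6|SERPINB9	-0.12878
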