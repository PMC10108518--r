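NA UGCAUG_like
PO A C G T
01 0.04 0.04 0.04 0.88
02 0.04 0.04 0.88 0.04
03 0.04 0.88 0.04 0.04
04 0.88 0.04 0.04 0.04
05 0.04 0.04 0.04 0.88
06 0.04 0.04 0.88 0.04
//
NA U_rich
PO A C G T
01 0.10 0.10 0.10 0.70
02 0.10 0.10 0.10 0.70
03 0.10 0.10 0.10 0.70
04 0.10 0.10 0.10 0.70
05 0.10 0.10 0.10 0.70
//
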