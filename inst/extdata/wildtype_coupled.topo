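Source Target Type Mechanism
SNAIL ZEB 1 T
SNAIL miR200 2 T
ZEB miR200 2 T
miR200 ZEB 2 R
ZEB ZEB 1 T
ZEB Ecad 2 T
Ecad ZEB 2 I
NFATc ZEB 1 T
NFATc miR200 1 T
NFATc Ecad 1 T
NFATc SNAIL 1 T
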