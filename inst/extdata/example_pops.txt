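Yanbian_1 Yanbian
Yanbian_2 Yanbian
Yanbian_3 Yanbian
Yanbian_4 Yanbian
Hanwoo_1 Hanwoo
Hanwoo_2 Hanwoo
Hanwoo_3 Hanwoo
Hanwoo_4 Hanwoo
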