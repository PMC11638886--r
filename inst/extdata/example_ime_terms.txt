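pt
Erectile dysfunction
Retrograde ejaculation
Haemorrhagic ovarian cyst
Ovarian cyst ruptured
Priapism
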