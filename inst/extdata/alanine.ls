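; TBDMS-alanine fragment (m0 259), 13C-labelled sample
Alanine (Ala)	259.15#260.1#261.1#262.1#263.1#264.1#265.1#	0.07#8.53#2.3#2.39#44.59#8.79#3.88#	3	3
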