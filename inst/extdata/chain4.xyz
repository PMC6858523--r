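4
planar 4-atom chain toy
C 0.0000000000 0.0000000000 0.0000000000
C 1.4000000000 0.4000000000 0.0000000000
C 2.8000000000 0.0000000000 0.0000000000
C 4.2000000000 0.4000000000 0.0000000000
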