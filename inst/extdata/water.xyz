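3
bent water-like toy (relaxed)
O -0.0167000000 -0.0212000000 0.0000000000
H 0.9298000000 0.0406000000 0.0000000000
H -0.1931000000 0.9107000000 0.0000000000
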