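protein_id
ACTB
ACTN1
TUBB
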