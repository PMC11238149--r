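protein_id	group
toy_s1	6A
toy_s2	6A
toy_s3	8
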