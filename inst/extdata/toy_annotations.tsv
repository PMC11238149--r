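protein_id	feature	start	end
toy_s1	CC	365	395
toy_s3	TM	370	392
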