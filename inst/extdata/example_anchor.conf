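# Example reference-anchor config using the packaged synthetic reference.
# Replace reference_fasta and the coordinates with a real septin anchor
# (e.g. the S. cerevisiae Cdc3 GTPase domain) for analyses of real data.
reference_fasta = synthetic_reference_septin.fasta
gtpase_start = 61
gtpase_end = 360
r_finger_col = 160
switch1_col = 110
coverage_floor = 0.5
gap_open = 10
gap_extend = 1
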