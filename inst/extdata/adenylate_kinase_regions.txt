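# Adenylate kinase subdomains (author numbering, chain A):
# the two mobile lids close over the core upon substrate binding.
ATP_lid A 26 78
CORE A 79 214
AMP_lid A 121 160
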