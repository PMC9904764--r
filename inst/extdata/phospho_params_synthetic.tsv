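# SYNTHETIC stand-in parameters for phosphoserine (pS) and phosphothreonine
# (pT) beads.  The published phospho extension of the HPS model is not
# redistributable here; these defaults map the hydropathy to aspartate
# (the same rule the KH variant uses for pair interactions), enlarge the
# bead diameter by 1.0 A for the phosphate group, and add its mass
# (79.97 g/mol).  The charge column is the -2e default; loadForceField()
# rewrites it to -1.5e when that mode is selected.
code	mass	charge	sigma	lambda
pS	167.05	-2	6.18	0.378
pT	181.07	-2	6.62	0.378
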