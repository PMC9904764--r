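# HPS alpha-carbon force-field parameters: one bead per residue.
# lambda: Kapcha-Rossky-derived hydropathy scale normalized to [0,1];
# sigma: van der Waals diameter (A); mass g/mol; charge in e at neutral pH
# (histidine neutral by default; see loadForceField(hisCharge=)).
code	mass	charge	sigma	lambda
A	71.08	0	5.04	0.730
R	156.19	1	6.56	0.000
N	114.10	0	5.68	0.432
D	115.09	-1	5.58	0.378
C	103.14	0	5.48	0.595
Q	128.13	0	6.02	0.514
E	129.11	-1	5.92	0.459
G	57.05	0	4.50	0.649
H	137.14	0	6.08	0.514
I	113.16	0	6.18	0.973
L	113.16	0	6.18	0.973
K	128.17	1	6.36	0.514
M	131.19	0	6.18	0.838
F	147.18	0	6.36	1.000
P	97.12	0	5.56	1.000
S	87.08	0	5.18	0.595
T	101.10	0	5.62	0.676
W	186.21	0	6.78	0.946
Y	163.18	0	6.46	0.865
V	99.07	0	5.86	0.892
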