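# SYNTHETIC stand-in for the Miyazawa-Jernigan residue-residue contact
# energy matrix (units kcal/mol as consumed by the KH model-D mapping).
# Constructed as e_ij = 1.0 - 2.5*(lambda_i + lambda_j) from the HPS
# hydropathy scale; NOT the published statistical potential.
code	A	R	N	D	C	Q	E	G	H	I	L	K	M	F	P	S	T	W	Y	V
A	-2.6500	-0.8250	-1.9050	-1.7700	-2.3125	-2.1100	-1.9725	-2.4475	-2.1100	-3.2575	-3.2575	-2.1100	-2.9200	-3.3250	-3.3250	-2.3125	-2.5150	-3.1900	-2.9875	-3.0550
R	-0.8250	1.0000	-0.0800	0.0550	-0.4875	-0.2850	-0.1475	-0.6225	-0.2850	-1.4325	-1.4325	-0.2850	-1.0950	-1.5000	-1.5000	-0.4875	-0.6900	-1.3650	-1.1625	-1.2300
N	-1.9050	-0.0800	-1.1600	-1.0250	-1.5675	-1.3650	-1.2275	-1.7025	-1.3650	-2.5125	-2.5125	-1.3650	-2.1750	-2.5800	-2.5800	-1.5675	-1.7700	-2.4450	-2.2425	-2.3100
D	-1.7700	0.0550	-1.0250	-0.8900	-1.4325	-1.2300	-1.0925	-1.5675	-1.2300	-2.3775	-2.3775	-1.2300	-2.0400	-2.4450	-2.4450	-1.4325	-1.6350	-2.3100	-2.1075	-2.1750
C	-2.3125	-0.4875	-1.5675	-1.4325	-1.9750	-1.7725	-1.6350	-2.1100	-1.7725	-2.9200	-2.9200	-1.7725	-2.5825	-2.9875	-2.9875	-1.9750	-2.1775	-2.8525	-2.6500	-2.7175
Q	-2.1100	-0.2850	-1.3650	-1.2300	-1.7725	-1.5700	-1.4325	-1.9075	-1.5700	-2.7175	-2.7175	-1.5700	-2.3800	-2.7850	-2.7850	-1.7725	-1.9750	-2.6500	-2.4475	-2.5150
E	-1.9725	-0.1475	-1.2275	-1.0925	-1.6350	-1.4325	-1.2950	-1.7700	-1.4325	-2.5800	-2.5800	-1.4325	-2.2425	-2.6475	-2.6475	-1.6350	-1.8375	-2.5125	-2.3100	-2.3775
G	-2.4475	-0.6225	-1.7025	-1.5675	-2.1100	-1.9075	-1.7700	-2.2450	-1.9075	-3.0550	-3.0550	-1.9075	-2.7175	-3.1225	-3.1225	-2.1100	-2.3125	-2.9875	-2.7850	-2.8525
H	-2.1100	-0.2850	-1.3650	-1.2300	-1.7725	-1.5700	-1.4325	-1.9075	-1.5700	-2.7175	-2.7175	-1.5700	-2.3800	-2.7850	-2.7850	-1.7725	-1.9750	-2.6500	-2.4475	-2.5150
I	-3.2575	-1.4325	-2.5125	-2.3775	-2.9200	-2.7175	-2.5800	-3.0550	-2.7175	-3.8650	-3.8650	-2.7175	-3.5275	-3.9325	-3.9325	-2.9200	-3.1225	-3.7975	-3.5950	-3.6625
L	-3.2575	-1.4325	-2.5125	-2.3775	-2.9200	-2.7175	-2.5800	-3.0550	-2.7175	-3.8650	-3.8650	-2.7175	-3.5275	-3.9325	-3.9325	-2.9200	-3.1225	-3.7975	-3.5950	-3.6625
K	-2.1100	-0.2850	-1.3650	-1.2300	-1.7725	-1.5700	-1.4325	-1.9075	-1.5700	-2.7175	-2.7175	-1.5700	-2.3800	-2.7850	-2.7850	-1.7725	-1.9750	-2.6500	-2.4475	-2.5150
M	-2.9200	-1.0950	-2.1750	-2.0400	-2.5825	-2.3800	-2.2425	-2.7175	-2.3800	-3.5275	-3.5275	-2.3800	-3.1900	-3.5950	-3.5950	-2.5825	-2.7850	-3.4600	-3.2575	-3.3250
F	-3.3250	-1.5000	-2.5800	-2.4450	-2.9875	-2.7850	-2.6475	-3.1225	-2.7850	-3.9325	-3.9325	-2.7850	-3.5950	-4.0000	-4.0000	-2.9875	-3.1900	-3.8650	-3.6625	-3.7300
P	-3.3250	-1.5000	-2.5800	-2.4450	-2.9875	-2.7850	-2.6475	-3.1225	-2.7850	-3.9325	-3.9325	-2.7850	-3.5950	-4.0000	-4.0000	-2.9875	-3.1900	-3.8650	-3.6625	-3.7300
S	-2.3125	-0.4875	-1.5675	-1.4325	-1.9750	-1.7725	-1.6350	-2.1100	-1.7725	-2.9200	-2.9200	-1.7725	-2.5825	-2.9875	-2.9875	-1.9750	-2.1775	-2.8525	-2.6500	-2.7175
T	-2.5150	-0.6900	-1.7700	-1.6350	-2.1775	-1.9750	-1.8375	-2.3125	-1.9750	-3.1225	-3.1225	-1.9750	-2.7850	-3.1900	-3.1900	-2.1775	-2.3800	-3.0550	-2.8525	-2.9200
W	-3.1900	-1.3650	-2.4450	-2.3100	-2.8525	-2.6500	-2.5125	-2.9875	-2.6500	-3.7975	-3.7975	-2.6500	-3.4600	-3.8650	-3.8650	-2.8525	-3.0550	-3.7300	-3.5275	-3.5950
Y	-2.9875	-1.1625	-2.2425	-2.1075	-2.6500	-2.4475	-2.3100	-2.7850	-2.4475	-3.5950	-3.5950	-2.4475	-3.2575	-3.6625	-3.6625	-2.6500	-2.8525	-3.5275	-3.3250	-3.3925
V	-3.0550	-1.2300	-2.3100	-2.1750	-2.7175	-2.5150	-2.3775	-2.8525	-2.5150	-3.6625	-3.6625	-2.5150	-3.3250	-3.7300	-3.7300	-2.7175	-2.9200	-3.5950	-3.3925	-3.4600
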