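# SYNTHETIC-membership phosphosite table for the Cdc15 IDR model system.
# Site counts and overlap structure follow the reported in vitro mapping
# (Pom1 22 sites, Shk1 11, Kin1 5, Pck1 1 [S668]; union of 31 sites on the
# IDR, residues 327-854).  Positions marked "reported" are documented
# Cdc15 phosphosites; positions marked "reconstructed", and all
# per-kinase memberships other than Pck1's S668, are plausible
# reconstructions, NOT the experimentally assigned sets.
site	residue	kinases	provenance
352	T	Shk1	reconstructed
367	S	Pom1	reconstructed
419	T	Pom1	reported
438	S	Shk1	reconstructed
462	T	Kin1	reconstructed
479	S	Shk1	reconstructed
492	T	Pom1	reported
511	S	Pom1,Shk1	reported
527	S	Pom1,Kin1	reported
556	S	Shk1	reconstructed
571	S	Shk1	reconstructed
597	T	Shk1	reconstructed
605	S	Pom1,Shk1	reported
636	S	Pom1	reported
668	S	Pom1,Pck1	reported
686	S	Kin1	reconstructed
702	S	Pom1,Shk1	reported
710	S	Pom1	reported
721	S	Pom1	reported
732	S	Pom1	reported
743	S	Pom1,Shk1	reported
752	S	Pom1	reported
774	S	Pom1	reported
785	S	Pom1	reported
786	S	Pom1,Kin1	reported
813	S	Pom1	reported
821	S	Pom1	reported
831	S	Pom1	reported
836	S	Pom1	reported
840	S	Pom1,Shk1	reported
847	T	Kin1	reconstructed
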