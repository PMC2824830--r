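# Nucleic Acid Database identifiers of the crystal forms whose packing
# crossovers the reference table (reference_crossovers.tsv) describes.
# The pipeline consumes coordinate files; place them (PDB or mmCIF format,
# named <ndb_id>.pdb / <ndb_id>.cif) in a directory and point
# batchAnalyze() or the regression test at it via the accessionDir helper
# documented in tests/testthat/test-acceptance.R. The pdb_id column is left
# blank where the mapping was not verifiable offline; fill it in before
# fetching from the wwPDB.
ndb_id	pdb_id	description
BD0022	.	B-DNA dodecamer ACCGGCGCCACA, R3, Mg
BD0015	.	B-DNA decamer CCGCCGGCGG, R3, Mg
BD0028	.	B-DNA decamer CCGCTAGCGG, C2
BD0047	.	B-DNA dodecamer GCAAACGTTTGC, P3121
BD0076	.	B-DNA decamer CCTCTAGAGG, C2
BDJ060	.	B-DNA decamer CTCTCGAGAG, C2, Ca
BDJ069	.	B-DNA decamer CGCAATTGCG, C2
BD0084	.	B-DNA decamer CCGAGCTCGG, P31
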