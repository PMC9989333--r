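# mutspectra rate matrix; normalized=FALSE overall_rate=NA
# SYNTHETIC stand-in for an empirically inferred context-specific matrix: transitions 3x transversions,
# CpG C>T transitions 12x (both strands). Not transcribed from any published table; for examples and tests only.
triplet	derived	rate
AAA	C	1
AAA	G	3
AAA	T	1
AAC	C	1
AAC	G	3
AAC	T	1
AAG	C	1
AAG	G	3
AAG	T	1
AAT	C	1
AAT	G	3
AAT	T	1
ACA	A	1
ACA	G	1
ACA	T	3
ACC	A	1
ACC	G	1
ACC	T	3
ACG	A	1
ACG	G	1
ACG	T	12
ACT	A	1
ACT	G	1
ACT	T	3
AGA	A	3
AGA	C	1
AGA	T	1
AGC	A	3
AGC	C	1
AGC	T	1
AGG	A	3
AGG	C	1
AGG	T	1
AGT	A	3
AGT	C	1
AGT	T	1
ATA	A	1
ATA	C	3
ATA	G	1
ATC	A	1
ATC	C	3
ATC	G	1
ATG	A	1
ATG	C	3
ATG	G	1
ATT	A	1
ATT	C	3
ATT	G	1
CAA	C	1
CAA	G	3
CAA	T	1
CAC	C	1
CAC	G	3
CAC	T	1
CAG	C	1
CAG	G	3
CAG	T	1
CAT	C	1
CAT	G	3
CAT	T	1
CCA	A	1
CCA	G	1
CCA	T	3
CCC	A	1
CCC	G	1
CCC	T	3
CCG	A	1
CCG	G	1
CCG	T	12
CCT	A	1
CCT	G	1
CCT	T	3
CGA	A	12
CGA	C	1
CGA	T	1
CGC	A	12
CGC	C	1
CGC	T	1
CGG	A	12
CGG	C	1
CGG	T	1
CGT	A	12
CGT	C	1
CGT	T	1
CTA	A	1
CTA	C	3
CTA	G	1
CTC	A	1
CTC	C	3
CTC	G	1
CTG	A	1
CTG	C	3
CTG	G	1
CTT	A	1
CTT	C	3
CTT	G	1
GAA	C	1
GAA	G	3
GAA	T	1
GAC	C	1
GAC	G	3
GAC	T	1
GAG	C	1
GAG	G	3
GAG	T	1
GAT	C	1
GAT	G	3
GAT	T	1
GCA	A	1
GCA	G	1
GCA	T	3
GCC	A	1
GCC	G	1
GCC	T	3
GCG	A	1
GCG	G	1
GCG	T	12
GCT	A	1
GCT	G	1
GCT	T	3
GGA	A	3
GGA	C	1
GGA	T	1
GGC	A	3
GGC	C	1
GGC	T	1
GGG	A	3
GGG	C	1
GGG	T	1
GGT	A	3
GGT	C	1
GGT	T	1
GTA	A	1
GTA	C	3
GTA	G	1
GTC	A	1
GTC	C	3
GTC	G	1
GTG	A	1
GTG	C	3
GTG	G	1
GTT	A	1
GTT	C	3
GTT	G	1
TAA	C	1
TAA	G	3
TAA	T	1
TAC	C	1
TAC	G	3
TAC	T	1
TAG	C	1
TAG	G	3
TAG	T	1
TAT	C	1
TAT	G	3
TAT	T	1
TCA	A	1
TCA	G	1
TCA	T	3
TCC	A	1
TCC	G	1
TCC	T	3
TCG	A	1
TCG	G	1
TCG	T	12
TCT	A	1
TCT	G	1
TCT	T	3
TGA	A	3
TGA	C	1
TGA	T	1
TGC	A	3
TGC	C	1
TGC	T	1
TGG	A	3
TGG	C	1
TGG	T	1
TGT	A	3
TGT	C	1
TGT	T	1
TTA	A	1
TTA	C	3
TTA	G	1
TTC	A	1
TTC	C	3
TTC	G	1
TTG	A	1
TTG	C	3
TTG	G	1
TTT	A	1
TTT	C	3
TTT	G	1
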