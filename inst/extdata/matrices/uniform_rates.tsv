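# mutspectra rate matrix; normalized=FALSE overall_rate=NA
# Jukes-Cantor uniform matrix: all 192 context-specific entries equal (arbitrary scale; normalize before use).
triplet	derived	rate
AAA	C	1
AAA	G	1
AAA	T	1
AAC	C	1
AAC	G	1
AAC	T	1
AAG	C	1
AAG	G	1
AAG	T	1
AAT	C	1
AAT	G	1
AAT	T	1
ACA	A	1
ACA	G	1
ACA	T	1
ACC	A	1
ACC	G	1
ACC	T	1
ACG	A	1
ACG	G	1
ACG	T	1
ACT	A	1
ACT	G	1
ACT	T	1
AGA	A	1
AGA	C	1
AGA	T	1
AGC	A	1
AGC	C	1
AGC	T	1
AGG	A	1
AGG	C	1
AGG	T	1
AGT	A	1
AGT	C	1
AGT	T	1
ATA	A	1
ATA	C	1
ATA	G	1
ATC	A	1
ATC	C	1
ATC	G	1
ATG	A	1
ATG	C	1
ATG	G	1
ATT	A	1
ATT	C	1
ATT	G	1
CAA	C	1
CAA	G	1
CAA	T	1
CAC	C	1
CAC	G	1
CAC	T	1
CAG	C	1
CAG	G	1
CAG	T	1
CAT	C	1
CAT	G	1
CAT	T	1
CCA	A	1
CCA	G	1
CCA	T	1
CCC	A	1
CCC	G	1
CCC	T	1
CCG	A	1
CCG	G	1
CCG	T	1
CCT	A	1
CCT	G	1
CCT	T	1
CGA	A	1
CGA	C	1
CGA	T	1
CGC	A	1
CGC	C	1
CGC	T	1
CGG	A	1
CGG	C	1
CGG	T	1
CGT	A	1
CGT	C	1
CGT	T	1
CTA	A	1
CTA	C	1
CTA	G	1
CTC	A	1
CTC	C	1
CTC	G	1
CTG	A	1
CTG	C	1
CTG	G	1
CTT	A	1
CTT	C	1
CTT	G	1
GAA	C	1
GAA	G	1
GAA	T	1
GAC	C	1
GAC	G	1
GAC	T	1
GAG	C	1
GAG	G	1
GAG	T	1
GAT	C	1
GAT	G	1
GAT	T	1
GCA	A	1
GCA	G	1
GCA	T	1
GCC	A	1
GCC	G	1
GCC	T	1
GCG	A	1
GCG	G	1
GCG	T	1
GCT	A	1
GCT	G	1
GCT	T	1
GGA	A	1
GGA	C	1
GGA	T	1
GGC	A	1
GGC	C	1
GGC	T	1
GGG	A	1
GGG	C	1
GGG	T	1
GGT	A	1
GGT	C	1
GGT	T	1
GTA	A	1
GTA	C	1
GTA	G	1
GTC	A	1
GTC	C	1
GTC	G	1
GTG	A	1
GTG	C	1
GTG	G	1
GTT	A	1
GTT	C	1
GTT	G	1
TAA	C	1
TAA	G	1
TAA	T	1
TAC	C	1
TAC	G	1
TAC	T	1
TAG	C	1
TAG	G	1
TAG	T	1
TAT	C	1
TAT	G	1
TAT	T	1
TCA	A	1
TCA	G	1
TCA	T	1
TCC	A	1
TCC	G	1
TCC	T	1
TCG	A	1
TCG	G	1
TCG	T	1
TCT	A	1
TCT	G	1
TCT	T	1
TGA	A	1
TGA	C	1
TGA	T	1
TGC	A	1
TGC	C	1
TGC	T	1
TGG	A	1
TGG	C	1
TGG	T	1
TGT	A	1
TGT	C	1
TGT	T	1
TTA	A	1
TTA	C	1
TTA	G	1
TTC	A	1
TTC	C	1
TTC	G	1
TTG	A	1
TTG	C	1
TTG	G	1
TTT	A	1
TTT	C	1
TTT	G	1
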