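# Synthetic gene/protein lexicon (stand-in for a trained gene tagger).
# One symbol or name per line; matching is case-sensitive and token-based.
p53
TP53
MDM2
ras
Ras
raf
Raf
MAPK
MEK
ERK
ERK1
ERK2
AKT
Akt
mTOR
PI3K
PI-3K
Wnt
WNT
Notch
JAK
JAK2
STAT
STAT3
PKA
PKC
EGFR
TGF
IGF-1
GSK3
CDK
CDK4
p38
JNK
Rac
Rac1
Rho
RhoA
NF-kB
Hedgehog
SHH
BRCA1
BRCA2
PTEN
MYC
KRAS
BRAF
VEGF
TNF
IL-6
CD2
TCR
FAS
Bcl-2
Bax
caspase-3
AMPK
PPAR
HIF-1
APP
PSEN1
APOE
BACE1
tau
phosphatidylinositol 3-kinase
mammalian target of rapamycin
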