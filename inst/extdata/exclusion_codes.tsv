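code	category
ALA	standard_aa
ARG	standard_aa
ASN	standard_aa
ASP	standard_aa
CYS	standard_aa
GLN	standard_aa
GLU	standard_aa
GLY	standard_aa
HIS	standard_aa
ILE	standard_aa
LEU	standard_aa
LYS	standard_aa
MET	standard_aa
PHE	standard_aa
PRO	standard_aa
SER	standard_aa
THR	standard_aa
TRP	standard_aa
TYR	standard_aa
VAL	standard_aa
HOH	non_polymer
ZN	non_polymer
CO	non_polymer
NA	non_polymer
CU	non_polymer
MG	non_polymer
CL	non_polymer
IOD	non_polymer
SO4	non_polymer
HG	non_polymer
NO2	non_polymer
UNK	non_polymer
N	non_polymer
CA	non_polymer
C	non_polymer
G	non_polymer
A	non_polymer
U	non_polymer
I	non_polymer
DC	non_polymer
DG	non_polymer
DA	non_polymer
DU	non_polymer
DT	non_polymer
DI	non_polymer
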