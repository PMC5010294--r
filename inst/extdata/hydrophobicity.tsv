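aa	index	partition
A	1.8	hydrophobic
R	-4.5	hydrophilic
N	-3.5	hydrophilic
D	-3.5	hydrophilic
C	2.5	hydrophilic
Q	-3.5	hydrophilic
E	-3.5	hydrophilic
G	-0.4	hydrophobic
H	-3.2	hydrophilic
I	4.5	hydrophobic
L	3.8	hydrophobic
K	-3.9	hydrophilic
M	1.9	hydrophobic
F	2.8	hydrophobic
P	-1.6	hydrophobic
S	-0.8	hydrophilic
T	-0.7	hydrophilic
W	-0.9	hydrophobic
Y	-1.3	hydrophobic
V	4.2	hydrophobic
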