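aa	class
A	hydrophobic
C	hydrophobic
D	negative
E	negative
F	aromatic
G	glycine
H	positive
I	hydrophobic
K	positive
L	hydrophobic
M	hydrophobic
N	polar
P	proline
Q	polar
R	positive
S	polar
T	polar
V	hydrophobic
W	aromatic
Y	aromatic
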