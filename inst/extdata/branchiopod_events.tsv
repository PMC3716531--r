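label	description	category
A	Hatching from resting or subitaneous egg	hatching
B	Presence of a naupliar nervous system	morphological
C	Naupliar SL-ir somata are expressed	morphological
D	Moveable naupliar appendages are present	morphological
E	Presence of a mandibular palp	morphological
F	Thoracic limb rows are visible	morphological
G	Telsonic longitudinal neurite bundles are present	morphological
H	Carapace anlagen appear dorsally	morphological
I	First molt	molt
J	Maxillulae and maxillae buds are present	morphological
K	Postnaupliar neuromeres are developed	morphological
L	Thoracic neuromeres are developed	morphological
M	Primordial anterior trunk limbs are present	morphological
N	Conical furcal rami are developed at the posterior end of the body	morphological
O	Second molt	molt
P	Postnaupliar SL-ir somata are expressed	morphological
Q	Three lateral appendage nerves are present	morphological
R	Moveable anterior trunk limbs are developed	morphological
S	Compound eye anlagen appear dorsally	morphological
T	Differentiation of the ventral food groove	morphological
U	Differentiated furcal rami are present at the posterior end of the body	morphological
V	Third molt	molt
W	Four nauplius eye cups are present	morphological
X	Anterior-most trunk limbs are almost completely differentiated	morphological
Y	Fourth molt	molt
Z	Optical neuropil anlagen appear in the protocerebrum	morphological
AA	Fifth molt	molt
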