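# condevol force field
[globals]
bond_k	8030
bond_ref_protein	0.381
bond_ref_rna	0.5
dielectric	80
debye_length	0.795
coulomb_cutoff	3.5
[beads]
A	protein	0	71.08
R	protein	1	156.19
N	protein	0	114.1
D	protein	-1	115.09
C	protein	0	103.14
Q	protein	0	128.13
E	protein	-1	129.12
G	protein	0	57.05
H	protein	0.5	137.14
I	protein	0	113.16
L	protein	0	113.16
K	protein	1	128.17
M	protein	0	131.2
F	protein	0	147.18
P	protein	0	97.12
S	protein	0	87.08
T	protein	0	101.1
W	protein	0	186.21
Y	protein	0	163.18
V	protein	0	99.13
U	rna	-1	306.17
[pairs]
A	A	0.455	0.46	2	1	1.38
A	R	0.5159215057	0.53	2	1	1.59
R	R	0.585	0.6	2	1	1.8
A	N	0.4212481454	0.48	2	1	1.44
R	N	0.4776504998	0.55	2	1	1.65
N	N	0.39	0.5	2	1	1.5
A	D	0.3845451859	0.48	2	1	1.44
R	D	0.4360332556	0.55	2	1	1.65
N	D	0.3560196624	0.5	2	1	1.5
D	D	0.325	0.5	2	1	1.5
A	C	0.5159215057	0.47	2	1	1.41
R	C	0.585	0.54	2	1	1.62
N	C	0.4776504998	0.49	2	1	1.47
D	C	0.4360332556	0.49	2	1	1.47
C	C	0.585	0.48	2	1	1.44
A	Q	0.4212481454	0.505	2	1	1.515
R	Q	0.4776504998	0.575	2	1	1.725
N	Q	0.39	0.525	2	1	1.575
D	Q	0.3560196624	0.525	2	1	1.575
C	Q	0.4776504998	0.515	2	1	1.545
Q	Q	0.39	0.55	2	1	1.65
A	E	0.3845451859	0.505	2	1	1.515
R	E	0.4360332556	0.575	2	1	1.725
N	E	0.3560196624	0.525	2	1	1.575
D	E	0.325	0.525	2	1	1.575
C	E	0.4360332556	0.515	2	1	1.545
Q	E	0.3560196624	0.55	2	1	1.65
E	E	0.325	0.55	2	1	1.65
A	G	0.3845451859	0.455	2	1	1.365
R	G	0.4360332556	0.525	2	1	1.575
N	G	0.3560196624	0.475	2	1	1.425
D	G	0.325	0.475	2	1	1.425
C	G	0.4360332556	0.465	2	1	1.395
Q	G	0.3560196624	0.5	2	1	1.5
E	G	0.325	0.5	2	1	1.5
G	G	0.325	0.45	2	1	1.35
A	H	0.4864154603	0.505	2	1	1.515
R	H	0.5515432893	0.575	2	1	1.725
N	H	0.45033321	0.525	2	1	1.575
D	H	0.4110960958	0.525	2	1	1.575
C	H	0.5515432893	0.515	2	1	1.545
Q	H	0.45033321	0.55	2	1	1.65
E	H	0.4110960958	0.55	2	1	1.65
G	H	0.4110960958	0.5	2	1	1.5
H	H	0.52	0.55	2	1	1.65
A	I	0.5438290172	0.505	2	1	1.515
R	I	0.6166441437	0.575	2	1	1.725
N	I	0.503487835	0.525	2	1	1.575
D	I	0.4596194078	0.525	2	1	1.575
C	I	0.6166441437	0.515	2	1	1.545
Q	I	0.503487835	0.55	2	1	1.65
E	I	0.4596194078	0.55	2	1	1.65
G	I	0.4596194078	0.5	2	1	1.5
H	I	0.5813776741	0.55	2	1	1.65
I	I	0.65	0.55	2	1	1.65
A	L	0.5438290172	0.505	2	1	1.515
R	L	0.6166441437	0.575	2	1	1.725
N	L	0.503487835	0.525	2	1	1.575
D	L	0.4596194078	0.525	2	1	1.575
C	L	0.6166441437	0.515	2	1	1.545
Q	L	0.503487835	0.55	2	1	1.65
E	L	0.4596194078	0.55	2	1	1.65
G	L	0.4596194078	0.5	2	1	1.5
H	L	0.5813776741	0.55	2	1	1.65
I	L	0.65	0.55	2	1	1.65
L	L	0.65	0.55	2	1	1.65
A	K	0.3651232669	0.505	2	1	1.515
R	K	0.4140108694	0.575	2	1	1.725
N	K	0.3380384594	0.525	2	1	1.575
D	K	0.3085854825	0.525	2	1	1.575
C	K	0.4140108694	0.515	2	1	1.545
Q	K	0.3380384594	0.55	2	1	1.65
E	K	0.3085854825	0.55	2	1	1.65
G	K	0.3085854825	0.5	2	1	1.5
H	K	0.390333191	0.55	2	1	1.65
I	K	0.4364057745	0.55	2	1	1.65
L	K	0.4364057745	0.55	2	1	1.65
K	K	0.293	0.55	2	1	1.65
A	M	0.5703726852	0.505	2	1	1.515
R	M	0.6467418341	0.575	2	1	1.725
N	M	0.5280624963	0.525	2	1	1.575
D	M	0.4820529017	0.525	2	1	1.575
C	M	0.6467418341	0.515	2	1	1.545
Q	M	0.5280624963	0.55	2	1	1.65
E	M	0.4820529017	0.55	2	1	1.65
G	M	0.4820529017	0.5	2	1	1.5
H	M	0.6097540488	0.55	2	1	1.65
I	M	0.6817257513	0.55	2	1	1.65
L	M	0.6817257513	0.55	2	1	1.65
K	M	0.4577062377	0.55	2	1	1.65
M	M	0.715	0.55	2	1	1.65
A	F	0.8424962908	0.53	2	1	1.59
R	F	0.9553009997	0.6	2	1	1.8
N	F	0.78	0.55	2	1	1.65
D	F	0.7120393248	0.55	2	1	1.65
C	F	0.9553009997	0.54	2	1	1.62
Q	F	0.78	0.575	2	1	1.725
E	F	0.7120393248	0.575	2	1	1.725
G	F	0.7120393248	0.525	2	1	1.575
H	F	0.9006664199	0.575	2	1	1.725
I	F	1.00697567	0.575	2	1	1.725
L	F	1.00697567	0.575	2	1	1.725
K	F	0.6760769187	0.575	2	1	1.725
M	F	1.056124993	0.575	2	1	1.725
F	F	1.56	0.6	2	1	1.8
A	P	0.4212481454	0.48	2	1	1.44
R	P	0.4776504998	0.55	2	1	1.65
N	P	0.39	0.5	2	1	1.5
D	P	0.3560196624	0.5	2	1	1.5
C	P	0.4776504998	0.49	2	1	1.47
Q	P	0.39	0.525	2	1	1.575
E	P	0.3560196624	0.525	2	1	1.575
G	P	0.3560196624	0.475	2	1	1.425
H	P	0.45033321	0.525	2	1	1.575
I	P	0.503487835	0.525	2	1	1.575
L	P	0.503487835	0.525	2	1	1.575
K	P	0.3380384594	0.525	2	1	1.575
M	P	0.5280624963	0.525	2	1	1.575
F	P	0.78	0.55	2	1	1.65
P	P	0.39	0.5	2	1	1.5
A	S	0.403596333	0.465	2	1	1.395
R	S	0.4576352259	0.535	2	1	1.605
N	S	0.3736575973	0.485	2	1	1.455
D	S	0.341101158	0.485	2	1	1.455
C	S	0.4576352259	0.475	2	1	1.425
Q	S	0.3736575973	0.51	2	1	1.53
E	S	0.341101158	0.51	2	1	1.53
G	S	0.341101158	0.46	2	1	1.38
H	S	0.4314626287	0.51	2	1	1.53
I	S	0.4823898838	0.51	2	1	1.53
L	S	0.4823898838	0.51	2	1	1.53
K	S	0.3238734321	0.51	2	1	1.53
M	S	0.5059347784	0.51	2	1	1.53
F	S	0.7473151945	0.535	2	1	1.605
P	S	0.3736575973	0.485	2	1	1.455
S	S	0.358	0.47	2	1	1.41
A	T	0.403596333	0.48	2	1	1.44
R	T	0.4576352259	0.55	2	1	1.65
N	T	0.3736575973	0.5	2	1	1.5
D	T	0.341101158	0.5	2	1	1.5
C	T	0.4576352259	0.49	2	1	1.47
Q	T	0.3736575973	0.525	2	1	1.575
E	T	0.341101158	0.525	2	1	1.575
G	T	0.341101158	0.475	2	1	1.425
H	T	0.4314626287	0.525	2	1	1.575
I	T	0.4823898838	0.525	2	1	1.575
L	T	0.4823898838	0.525	2	1	1.575
K	T	0.3238734321	0.525	2	1	1.575
M	T	0.5059347784	0.525	2	1	1.575
F	T	0.7473151945	0.55	2	1	1.65
P	T	0.3736575973	0.5	2	1	1.5
S	T	0.358	0.485	2	1	1.455
T	T	0.358	0.5	2	1	1.5
A	W	0.8768979416	0.545	2	1	1.635
R	W	0.9943088052	0.615	2	1	1.845
N	W	0.8118497398	0.565	2	1	1.695
D	W	0.7411140263	0.565	2	1	1.695
C	W	0.9943088052	0.555	2	1	1.665
Q	W	0.8118497398	0.59	2	1	1.77
E	W	0.7411140263	0.59	2	1	1.77
G	W	0.7411140263	0.54	2	1	1.62
H	W	0.9374433316	0.59	2	1	1.77
I	W	1.048093507	0.59	2	1	1.77
L	W	1.048093507	0.59	2	1	1.77
K	W	0.7036831673	0.59	2	1	1.77
M	W	1.099249744	0.59	2	1	1.77
F	W	1.62369948	0.615	2	1	1.845
P	W	0.8118497398	0.565	2	1	1.695
S	W	0.7778303157	0.55	2	1	1.65
T	W	0.7778303157	0.565	2	1	1.695
W	W	1.69	0.63	2	1	1.89
A	Y	0.806628787	0.53	2	1	1.59
R	Y	0.9146310732	0.6	2	1	1.8
N	Y	0.746793144	0.55	2	1	1.65
D	Y	0.6817257513	0.55	2	1	1.65
C	Y	0.9146310732	0.54	2	1	1.62
Q	Y	0.746793144	0.575	2	1	1.725
E	Y	0.6817257513	0.575	2	1	1.725
G	Y	0.6817257513	0.525	2	1	1.575
H	Y	0.8623224455	0.575	2	1	1.725
I	Y	0.9641058033	0.575	2	1	1.725
L	Y	0.9641058033	0.575	2	1	1.725
K	Y	0.6472943689	0.575	2	1	1.725
M	Y	1.011162697	0.575	2	1	1.725
F	Y	1.493586288	0.6	2	1	1.8
P	Y	0.746793144	0.55	2	1	1.65
S	Y	0.7154998253	0.535	2	1	1.605
T	Y	0.7154998253	0.55	2	1	1.65
W	Y	1.554573897	0.615	2	1	1.845
Y	Y	1.43	0.6	2	1	1.8
A	V	0.5159215057	0.48	2	1	1.44
R	V	0.585	0.55	2	1	1.65
N	V	0.4776504998	0.5	2	1	1.5
D	V	0.4360332556	0.5	2	1	1.5
C	V	0.585	0.49	2	1	1.47
Q	V	0.4776504998	0.525	2	1	1.575
E	V	0.4360332556	0.525	2	1	1.575
G	V	0.4360332556	0.475	2	1	1.425
H	V	0.5515432893	0.525	2	1	1.575
I	V	0.6166441437	0.525	2	1	1.575
L	V	0.6166441437	0.525	2	1	1.575
K	V	0.4140108694	0.525	2	1	1.575
M	V	0.6467418341	0.525	2	1	1.575
F	V	0.9553009997	0.55	2	1	1.65
P	V	0.4776504998	0.5	2	1	1.5
S	V	0.4576352259	0.485	2	1	1.455
T	V	0.4576352259	0.5	2	1	1.5
W	V	0.9943088052	0.565	2	1	1.695
Y	V	0.9146310732	0.55	2	1	1.65
V	V	0.585	0.5	2	1	1.5
A	U	0.6434671709	0.555	2	1	1.665
R	U	1.1	0.625	2	1	1.875
N	U	0.5957348403	0.575	2	1	1.725
D	U	0.5438290172	0.575	2	1	1.725
C	U	0.7296231904	0.565	2	1	1.695
Q	U	0.5957348403	0.6	2	1	1.8
E	U	0.5438290172	0.6	2	1	1.8
G	U	0.5438290172	0.55	2	1	1.65
H	U	0.6878953409	0.6	2	1	1.8
I	U	0.7690903718	0.6	2	1	1.8
L	U	0.7690903718	0.6	2	1	1.8
K	U	0.55	0.6	2	1	1.8
M	U	0.806628787	0.6	2	1	1.8
F	U	1.191469681	0.625	2	1	1.875
P	U	0.5957348403	0.575	2	1	1.725
S	U	0.5707714078	0.56	2	1	1.68
T	U	0.5707714078	0.575	2	1	1.725
W	U	1.240120962	0.64	2	1	1.92
Y	U	1.14074537	0.625	2	1	1.875
V	U	0.7296231904	0.575	2	1	1.725
U	U	0.91	0.65	2	1	1.95
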