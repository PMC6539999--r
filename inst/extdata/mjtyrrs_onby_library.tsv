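position	library	onbyrs1
Y32	A, S	A
L65	A, I, L, F, S	A
A67	A, Q	A
L69	L, K, G, W	L
H70	A, N, S	N
G105	G, A, Q	Q
F108	F, L	F
Q109	A, Q, Y	A
M154	E, M, T, G	M
D158	A, G, S	S
I159	A, G, S, I	A
L162	A, M	A
V164	A, T, V	V
A167	N, Q, G, S	S
H177	A, H, Q, Y	H
A180	A, Q	Q
V188	N, Q, T, V	V
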