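# Synthetic average chemical shift table (ppm), one row per (residue, state, nucleus).
# Values are random-coil backbone shifts plus fixed helix/sheet secondary-shift
# offsets -- a realistic stand-in for server-derived ACS reference values, NOT
# measured data. Columns: residue state nucleus value
residue	state	nucleus	value
A	H	N15	122.30
A	H	CA13	 55.10
A	H	HA1	  3.94
A	H	HN1	  8.04
A	E	N15	125.80
A	E	CA13	 51.30
A	E	HA1	  4.70
A	E	HN1	  8.54
A	C	N15	123.80
A	C	CA13	 52.50
A	C	HA1	  4.32
A	C	HN1	  8.24
C	H	N15	117.30
C	H	CA13	 60.80
C	H	HA1	  4.17
C	H	HN1	  8.12
C	E	N15	120.80
C	E	CA13	 57.00
C	E	HA1	  4.93
C	E	HN1	  8.62
C	C	N15	118.80
C	C	CA13	 58.20
C	C	HA1	  4.55
C	C	HN1	  8.32
D	H	N15	118.90
D	H	CA13	 56.80
D	H	HA1	  4.26
D	H	HN1	  8.14
D	E	N15	122.40
D	E	CA13	 53.00
D	E	HA1	  5.02
D	E	HN1	  8.64
D	C	N15	120.40
D	C	CA13	 54.20
D	C	HA1	  4.64
D	C	HN1	  8.34
E	H	N15	118.70
E	H	CA13	 59.20
E	H	HA1	  3.97
E	H	HN1	  8.22
E	E	N15	122.20
E	E	CA13	 55.40
E	E	HA1	  4.73
E	E	HN1	  8.72
E	C	N15	120.20
E	C	CA13	 56.60
E	C	HA1	  4.35
E	C	HN1	  8.42
F	H	N15	118.80
F	H	CA13	 60.30
F	H	HA1	  4.24
F	H	HN1	  8.10
F	E	N15	122.30
F	E	CA13	 56.50
F	E	HA1	  5.00
F	E	HN1	  8.60
F	C	N15	120.30
F	C	CA13	 57.70
F	C	HA1	  4.62
F	C	HN1	  8.30
G	H	N15	107.30
G	H	CA13	 47.70
G	H	HA1	  3.58
G	H	HN1	  8.13
G	E	N15	110.80
G	E	CA13	 43.90
G	E	HA1	  4.34
G	E	HN1	  8.63
G	C	N15	108.80
G	C	CA13	 45.10
G	C	HA1	  3.96
G	C	HN1	  8.33
H	H	N15	116.70
H	H	CA13	 57.60
H	H	HA1	  4.35
H	H	HN1	  8.22
H	E	N15	120.20
H	E	CA13	 53.80
H	E	HA1	  5.11
H	E	HN1	  8.72
H	C	N15	118.20
H	C	CA13	 55.00
H	C	HA1	  4.73
H	C	HN1	  8.42
I	H	N15	118.40
I	H	CA13	 63.70
I	H	HA1	  3.79
I	H	HN1	  7.80
I	E	N15	121.90
I	E	CA13	 59.90
I	E	HA1	  4.55
I	E	HN1	  8.30
I	C	N15	119.90
I	C	CA13	 61.10
I	C	HA1	  4.17
I	C	HN1	  8.00
K	H	N15	118.90
K	H	CA13	 58.80
K	H	HA1	  3.94
K	H	HN1	  8.09
K	E	N15	122.40
K	E	CA13	 55.00
K	E	HA1	  4.70
K	E	HN1	  8.59
K	C	N15	120.40
K	C	CA13	 56.20
K	C	HA1	  4.32
K	C	HN1	  8.29
L	H	N15	120.30
L	H	CA13	 57.70
L	H	HA1	  3.96
L	H	HN1	  7.96
L	E	N15	123.80
L	E	CA13	 53.90
L	E	HA1	  4.72
L	E	HN1	  8.46
L	C	N15	121.80
L	C	CA13	 55.10
L	C	HA1	  4.34
L	C	HN1	  8.16
M	H	N15	118.10
M	H	CA13	 58.00
M	H	HA1	  4.10
M	H	HN1	  8.08
M	E	N15	121.60
M	E	CA13	 54.20
M	E	HA1	  4.86
M	E	HN1	  8.58
M	C	N15	119.60
M	C	CA13	 55.40
M	C	HA1	  4.48
M	C	HN1	  8.28
N	H	N15	117.20
N	H	CA13	 55.70
N	H	HA1	  4.36
N	H	HN1	  8.20
N	E	N15	120.70
N	E	CA13	 51.90
N	E	HA1	  5.12
N	E	HN1	  8.70
N	C	N15	118.70
N	C	CA13	 53.10
N	C	HA1	  4.74
N	C	HN1	  8.40
P	H	N15	135.50
P	H	CA13	 65.90
P	H	HA1	  4.04
P	H	HN1	  8.10
P	E	N15	139.00
P	E	CA13	 62.10
P	E	HA1	  4.80
P	E	HN1	  8.60
P	C	N15	137.00
P	C	CA13	 63.30
P	C	HA1	  4.42
P	C	HN1	  8.30
Q	H	N15	118.30
Q	H	CA13	 58.30
Q	H	HA1	  3.96
Q	H	HN1	  8.12
Q	E	N15	121.80
Q	E	CA13	 54.50
Q	E	HA1	  4.72
Q	E	HN1	  8.62
Q	C	N15	119.80
Q	C	CA13	 55.70
Q	C	HA1	  4.34
Q	C	HN1	  8.32
R	H	N15	119.00
R	H	CA13	 58.60
R	H	HA1	  3.96
R	H	HN1	  8.07
R	E	N15	122.50
R	E	CA13	 54.80
R	E	HA1	  4.72
R	E	HN1	  8.57
R	C	N15	120.50
R	C	CA13	 56.00
R	C	HA1	  4.34
R	C	HN1	  8.27
S	H	N15	114.20
S	H	CA13	 60.90
S	H	HA1	  4.09
S	H	HN1	  8.11
S	E	N15	117.70
S	E	CA13	 57.10
S	E	HA1	  4.85
S	E	HN1	  8.61
S	C	N15	115.70
S	C	CA13	 58.30
S	C	HA1	  4.47
S	C	HN1	  8.31
T	H	N15	112.10
T	H	CA13	 64.40
T	H	HA1	  3.97
T	H	HN1	  7.95
T	E	N15	115.60
T	E	CA13	 60.60
T	E	HA1	  4.73
T	E	HN1	  8.45
T	C	N15	113.60
T	C	CA13	 61.80
T	C	HA1	  4.35
T	C	HN1	  8.15
V	H	N15	117.70
V	H	CA13	 64.80
V	H	HA1	  3.74
V	H	HN1	  7.83
V	E	N15	121.20
V	E	CA13	 61.00
V	E	HA1	  4.50
V	E	HN1	  8.33
V	C	N15	119.20
V	C	CA13	 62.20
V	C	HA1	  4.12
V	C	HN1	  8.03
W	H	N15	119.80
W	H	CA13	 60.10
W	H	HA1	  4.28
W	H	HN1	  8.05
W	E	N15	123.30
W	E	CA13	 56.30
W	E	HA1	  5.04
W	E	HN1	  8.55
W	C	N15	121.30
W	C	CA13	 57.50
W	C	HA1	  4.66
W	C	HN1	  8.25
Y	H	N15	118.80
Y	H	CA13	 60.50
Y	H	HA1	  4.17
Y	H	HN1	  7.92
Y	E	N15	122.30
Y	E	CA13	 56.70
Y	E	HA1	  4.93
Y	E	HN1	  8.42
Y	C	N15	120.30
Y	C	CA13	 57.90
Y	C	HA1	  4.55
Y	C	HN1	  8.12
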