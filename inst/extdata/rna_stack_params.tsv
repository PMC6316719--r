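step	dg
AA	-0.93
AU	-1.10
UA	-1.33
CU	-2.08
CA	-2.11
GU	-2.24
GA	-2.35
CG	-2.36
GG	-3.26
GC	-3.42
UU	-0.93
AG	-2.08
UG	-2.11
AC	-2.24
UC	-2.35
CC	-3.26
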