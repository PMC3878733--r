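outer	inner	dG
AT	AT	-0.9
AT	CG	-2.2
AT	GC	-2.1
AT	GT	-0.6
AT	TA	-1.1
AT	TG	-1.4
CG	AT	-2.1
CG	CG	-3.3
CG	GC	-2.4
CG	GT	-1.4
CG	TA	-2.1
CG	TG	-2.1
GC	AT	-2.4
GC	CG	-3.4
GC	GC	-3.3
GC	GT	-1.5
GC	TA	-2.2
GC	TG	-2.5
GT	AT	-1.3
GT	CG	-2.5
GT	GC	-2.1
GT	GT	-0.5
GT	TA	-1.4
GT	TG	1.3
TA	AT	-1.3
TA	CG	-2.4
TA	GC	-2.1
TA	GT	-1
TA	TA	-0.9
TA	TG	-1.3
TG	AT	-1
TG	CG	-1.5
TG	GC	-1.4
TG	GT	0.3
TG	TA	-0.6
TG	TG	-0.5
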