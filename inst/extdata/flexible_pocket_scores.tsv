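target	ppi	method	pdb_id	score
CDK2	no	docking	1aq1	1.32
CDK2	no	docking	1buh	1.44
CDK2	no	docking	1dm2	1.62
CDK2	no	flexible	1aq1	1.7
CDK2	no	flexible	1buh	1.7
CDK2	no	flexible	1dm2	1.9
ER	no	docking	1l2i	1.69
ER	no	docking	3ert	1.55
ER	no	docking	1err	1.61
ER	no	flexible	1l2i	2.9
ER	no	flexible	3ert	2.7
ER	no	flexible	1err	2.8
HIV-RT	no	docking	1vrt	1.66
HIV-RT	no	docking	1rt1	1.75
HIV-RT	no	docking	1c1c	1.61
HIV-RT	no	docking	1rth	1.61
HIV-RT	no	flexible	1vrt	2.5
HIV-RT	no	flexible	1rt1	2.3
HIV-RT	no	flexible	1c1c	2.2
HIV-RT	no	flexible	1rth	2.3
p38a	no	docking	1a9u	1.00
p38a	no	docking	1kv1	1.16
p38a	no	docking	1kv2	1.61
p38a	no	flexible	1a9u	1.8
p38a	no	flexible	1kv1	2.1
p38a	no	flexible	1kv2	2.1
PPARg	no	docking	1fm6	1.46
PPARg	no	docking	1fm9	1.62
PPARg	no	docking	2prg	1.43
PPARg	no	flexible	1fm6	2.9
PPARg	no	flexible	1fm9	3.0
PPARg	no	flexible	2prg	2.1
TK	no	docking	1kim	1.58
TK	no	docking	1ki4	1.40
TK	no	flexible	1kim	2.7
TK	no	flexible	1ki4	2.6
IL-2	yes	docking	1z92	0.13
IL-2	yes	docking	1py2	0.62
IL-2	yes	docking	1m48	0.62
IL-2	yes	flexible	1z92	1.5
IL-2	yes	flexible	1py2	1.5
IL-2	yes	flexible	1m48	1.7
Bcl-xL	yes	docking	2bzw	1.04
Bcl-xL	yes	docking	2yxj	0.84
Bcl-xL	yes	flexible	2bzw	2.4
Bcl-xL	yes	flexible	2yxj	2.5
TNF	yes	docking	1tnf	0.95
TNF	yes	docking	2az5	0.96
TNF	yes	flexible	1tnf	2.4
TNF	yes	flexible	2az5	2.0
MDM2	yes	docking	1ycr	0.45
MDM2	yes	docking	1rv1	0.92
MDM2	yes	docking	1t4e	0.66
MDM2	yes	flexible	1ycr	2.5
MDM2	yes	flexible	1rv1	2.2
MDM2	yes	flexible	1t4e	2.1
HPV-E2	yes	docking	1tue	-0.24
HPV-E2	yes	docking	1r6n	1.02
HPV-E2	yes	flexible	1tue	1.1
HPV-E2	yes	flexible	1r6n	1.5
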