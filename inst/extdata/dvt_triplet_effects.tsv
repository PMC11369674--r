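exposure	mediator	outcome	c	a	b
PC(17:0/20:4)	SIRT2	DVT	0.0015	-0.0435	0.0024
PC(18:0/20:4)	SIRT2	DVT	0.0013	-0.0440	0.0024
PC(14:0/18:2)	CCL20	DVT	-0.0014	0.0670	0.0021
PC(15:0/18:2)	CCL20	DVT	-0.0012	0.0445	0.0021
PC(18:0/20:5)	CCL20	DVT	0.0016	-0.054	0.0021
TAG(58:7)	CCL20	DVT	0.0014	0.0850	0.0021
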