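model	lnl	k	reported_aic
DEC	-115.09205	2	234.184098
DEC+J	-113.31082	3	232.621645
DIVALIKE	-115.63941	2	235.278824
DIVALIKE+J	-115.64036	3	237.280724
BAYAREALIKE	-121.933	2	247.865999
BAYAREALIKE+J	-110.39081	3	226.78162
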