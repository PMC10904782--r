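ko	module_id	is_mm
K00577	M00567	1
K00577	M00357	1
K10946	M00174	1
K00205	M00567	1
K08685	M00346	1
K12234	M00937	1
K12235	M00937	1
K00441	M00937	1
K00441	M00567	1
K00600	M00346	1
K00600	M00141	0
K00925	M00357	1
K00925	M00579	0
K00625	M00357	1
K00625	M00579	0
K00198	M00567	1
K00198	M00377	0
K01895	M00357	1
K01895	M00579	0
K00845	M00001	0
K01689	M00001	0
K01689	M00002	0
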