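ko	pfam_acc
K00577	PF09472
K10946	PF04896
K00205	PF13247
K08685	PF01913
K12234	PF01996
K12235	PF08445
K00441	PF04432
K00600	PF00464
K00925	PF00871
K00625	PF01515
K00198	PF03063
K01895	PF16177
K00845	PF02685
K01689	PF00113
K03594	PF00210
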