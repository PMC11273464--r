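Label	Accuracy	Precision	TNR	ROC	PRC	Recall	F_Score
Breed_category	85.43	0.856	0.927	0.965	0.938	0.854	0.850
Pet_category	86.80	0.869	0.928	0.946	0.928	0.868	0.865
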