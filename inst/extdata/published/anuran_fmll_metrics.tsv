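Label	Accuracy	Precision	TNR	ROC	PRC	Recall	F_Score
Family	95.75	0.957	0.980	0.978	0.964	0.957	0.957
Genus	94.19	0.941	0.991	0.979	0.943	0.942	0.941
Species	93.55	0.935	0.992	0.983	0.935	0.936	0.935
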