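Label	Accuracy	Precision	TNR	ROC	PRC	Recall	F_Score
Green frogs	68.78	0.694	0.688	0.715	0.682	0.688	0.689
Brown frogs	78.31	0.613	0.783	0.503	0.665	0.783	0.688
Common toad	71.43	0.712	0.714	0.621	0.653	0.714	0.674
Fire-bellied toad	70.37	0.669	0.704	0.576	0.612	0.704	0.650
Tree frog	65.61	0.639	0.655	0.638	0.627	0.656	0.631
Common newt	69.84	0.658	0.698	0.528	0.603	0.698	0.619
Great crested newt	88.36	0.790	0.884	0.539	0.818	0.884	0.834
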