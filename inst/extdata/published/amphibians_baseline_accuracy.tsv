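Method	Accuracy	Role
Gradient-Boosted Trees (GBT)	64.18	baseline
Random Forest (RF)	57.54	baseline
AdaBoost (ADA)	60.01	baseline
Decision Tree (DT)	58.37	baseline
Partially Monotonic Decision Tree (PMDT)	71.50	baseline
FMLL with BR and REPTree	73.24	proposed
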