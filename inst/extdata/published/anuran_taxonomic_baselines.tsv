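Level	Method	Precision	Recall	F_Score	Role
Species	KNN-Flat	0.690	0.720	0.700	baseline
Species	RBF-SVM-Flat	0.850	0.540	0.660	baseline
Species	Polynomial-SVM-Flat	0.710	0.760	0.740	baseline
Species	Tree-Flat	0.490	0.500	0.500	baseline
Species	KNN-LCPL	0.691	0.719	0.705	baseline
Species	KNN-Hierarchical-LCPN	0.690	0.720	0.700	baseline
Species	RBF-SVM-Hierarchical-LCPN	0.840	0.540	0.650	baseline
Species	Polynomial-SVM-Hierarchical-LCPN	0.680	0.710	0.700	baseline
Species	Tree-Hierarchical-LCPN	0.570	0.560	0.560	baseline
Species	KNN-Hierarchical-LCPL	0.690	0.720	0.700	baseline
Species	RBF-SVM-Hierarchical-LCPL	0.830	0.520	0.640	baseline
Species	Polynomial-SVM-Hierarchical-LCPL	0.690	0.740	0.720	baseline
Species	Tree-Hierarchical-LCPL	0.470	0.500	0.490	baseline
Species	FMLL with BR and REPTree	0.935	0.936	0.935	proposed
Family	KNN-LCPL	0.713	0.820	0.763	baseline
Family	FMLL with BR and REPTree	0.957	0.957	0.957	proposed
Genus	KNN-LCPL	0.663	0.731	0.695	baseline
Genus	FMLL with BR and REPTree	0.941	0.942	0.941	proposed
Combined	KNN-LCPL	0.689	0.757	0.721	baseline
Combined	FMLL with BR and REPTree	0.944	0.945	0.944	proposed
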