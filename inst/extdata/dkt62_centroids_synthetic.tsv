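parcel_id	hemisphere	x	y	z
lh.caudalanteriorcingulate	left	-0.145408	-0.174855	-0.973798
lh.caudalmiddlefrontal	left	-0.448128	-0.017175	-0.893804
lh.cuneus	left	-0.42271	0.317507	-0.848826
lh.entorhinal	left	-0.099068	0.642959	-0.759466
lh.fusiform	left	-0.365252	-0.620629	-0.693838
lh.inferiorparietal	left	-0.746254	-0.215856	-0.629691
lh.inferiortemporal	left	-0.720316	0.372734	-0.58499
lh.isthmuscingulate	left	-0.309804	0.7923	-0.525625
lh.lateraloccipital	left	-0.301234	-0.827211	-0.474321
lh.lateralorbitofrontal	left	-0.836254	-0.386626	-0.388844
lh.lingual	left	-0.903843	0.284494	-0.31958
lh.medialorbitofrontal	left	-0.440108	0.853817	-0.27803
lh.middletemporal	left	-0.233262	-0.951631	-0.199969
lh.parahippocampal	left	-0.801641	-0.586595	-0.115233
lh.paracentral	left	-0.989427	0.136502	-0.04901
lh.parsopercularis	left	-0.64499	0.764133	0.00947
lh.parsorbitalis	left	-0.048346	-0.997666	0.048226
lh.parstriangularis	left	-0.72281	-0.683358	0.102798
lh.pericalcarine	left	-0.976692	-0.030572	0.212456
lh.postcentral	left	-0.72552	0.634315	0.266956
lh.posteriorcingulate	left	-0.134136	0.934852	0.328724
lh.precentral	left	-0.565003	-0.728924	0.386575
lh.precuneus	left	-0.882714	-0.184812	0.432042
lh.rostralanteriorcingulate	left	-0.726599	0.432242	0.53406
lh.rostralmiddlefrontal	left	-0.211001	0.786593	0.580302
lh.superiorfrontal	left	-0.332031	-0.686133	0.647284
lh.superiorparietal	left	-0.644634	-0.265896	0.716761
lh.superiortemporal	left	-0.616564	0.150864	0.772715
lh.supramarginal	left	-0.238448	0.476355	0.846303
lh.transversetemporal	left	-0.122682	-0.424034	0.897298
lh.insula	left	-0.200753	-0.131213	0.970815
rh.caudalanteriorcingulate	right	0.145408	-0.174855	-0.973798
rh.caudalmiddlefrontal	right	0.448128	-0.017175	-0.893804
rh.cuneus	right	0.42271	0.317507	-0.848826
rh.entorhinal	right	0.099068	0.642959	-0.759466
rh.fusiform	right	0.365252	-0.620629	-0.693838
rh.inferiorparietal	right	0.746254	-0.215856	-0.629691
rh.inferiortemporal	right	0.720316	0.372734	-0.58499
rh.isthmuscingulate	right	0.309804	0.7923	-0.525625
rh.lateraloccipital	right	0.301234	-0.827211	-0.474321
rh.lateralorbitofrontal	right	0.836254	-0.386626	-0.388844
rh.lingual	right	0.903843	0.284494	-0.31958
rh.medialorbitofrontal	right	0.440108	0.853817	-0.27803
rh.middletemporal	right	0.233262	-0.951631	-0.199969
rh.parahippocampal	right	0.801641	-0.586595	-0.115233
rh.paracentral	right	0.989427	0.136502	-0.04901
rh.parsopercularis	right	0.64499	0.764133	0.00947
rh.parsorbitalis	right	0.048346	-0.997666	0.048226
rh.parstriangularis	right	0.72281	-0.683358	0.102798
rh.pericalcarine	right	0.976692	-0.030572	0.212456
rh.postcentral	right	0.72552	0.634315	0.266956
rh.posteriorcingulate	right	0.134136	0.934852	0.328724
rh.precentral	right	0.565003	-0.728924	0.386575
rh.precuneus	right	0.882714	-0.184812	0.432042
rh.rostralanteriorcingulate	right	0.726599	0.432242	0.53406
rh.rostralmiddlefrontal	right	0.211001	0.786593	0.580302
rh.superiorfrontal	right	0.332031	-0.686133	0.647284
rh.superiorparietal	right	0.644634	-0.265896	0.716761
rh.superiortemporal	right	0.616564	0.150864	0.772715
rh.supramarginal	right	0.238448	0.476355	0.846303
rh.transversetemporal	right	0.122682	-0.424034	0.897298
rh.insula	right	0.200753	-0.131213	0.970815
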