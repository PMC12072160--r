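log2fc	protein
1.571257	Coatomer subunit epsilon
1.927359	Alpha-N-acetylglucosaminidase
1.894740	Cation-independent mannose-6-phosphate receptor
2.054181	Peroxidasin homolog
1.580536	Gamma-glutamyl hydrolase
3.314857	Protein CutA
2.227123	Glia maturation factor beta
2.208065	Apolipoprotein E
2.532013	Heat shock 70 kDa protein 4
1.578419	Collagen alpha-1(VIII) chain
1.601187	Microtubule-associated protein 4
2.059668	Cell growth regulator with EF hand domain protein 1
3.221587	Serine/threonine-protein phosphatase CPPED1
1.655928	Matrilin-2
1.663284	Beta-hexosaminidase subunit beta
1.599876	Clathrin heavy chain 1
2.113103	Complement factor B
2.010879	Myosin-9
1.582737	Prothrombin
1.606319	Pigment epithelium-derived factor
1.586922	Hemicentin-1
3.040665	DNA damage-binding protein 1
3.919236	Fatty acid synthase
3.001855	Keratin, type II cytoskeletal 2 epidermal
1.590041	Hemopexin
-2.236920	Actin-related protein 2
-1.603070	Purine nucleoside phosphorylase
-2.792950	Destrin
-1.902960	Zyxin
-1.528480	Puromycin-sensitive aminopeptidase
-1.906180	Xaa-Pro dipeptidase
-2.784430	Inter-alpha-trypsin inhibitor heavy chain H1
-2.081020	Proliferating cell nuclear antigen
-3.820350	Neuropilin-2
-2.276680	Protein disulfide-isomerase A4
-1.822280	Cytochrome c
-1.748530	Peroxiredoxin-6
-1.976610	Target of Nesh-SH3
-1.507560	Adenylyl cyclase-associated protein 1
-1.812880	60S ribosomal protein L12
-3.481370	Di-N-acetylchitobiase
-3.813460	Heat shock protein HSP 90-alpha
-3.231230	Plectin
-1.590510	CD9 antigen
-1.634060	Keratin, type I cytoskeletal 18
-2.157510	Endoplasmin
-2.517080	Stathmin
-1.552160	Isoform 3 of Tropomyosin alpha-1 chain
-2.465080	Vinculin
-1.786700	Alpha-actinin-1
-2.599790	Tubulin beta chain
-2.550980	Keratin, type II cytoskeletal 1
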