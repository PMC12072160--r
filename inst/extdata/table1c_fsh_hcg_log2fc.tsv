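log2fc	protein
1.785251	Alpha-N-acetylglucosaminidase
1.873705	F-actin-capping protein subunit alpha-2
3.283473	Protein CutA
1.913249	Heat shock 70 kDa protein 4
2.007756	Cytosolic non-specific dipeptidase
1.661596	1,4-alpha-glucan-branching enzyme
2.652092	Peroxidasin homolog
2.316264	Apolipoprotein B-100
1.710004	Receptor of activated protein C kinase 1
2.013970	Twisted gastrulation protein homolog 1
1.562129	Semaphorin-7A
1.994896	Clathrin heavy chain 1
3.373673	Gamma-glutamyl hydrolase
1.555267	Integrin beta-1
2.400909	Complement factor B
1.849335	Pigment epithelium-derived factor
2.055622	Prothrombin
4.180675	Fatty acid synthase
1.517620	Afamin
1.886488	Nucleobindin-1
2.397546	Gamma-enolase
2.673931	Malate dehydrogenase
3.685358	Keratin, type II cytoskeletal 2 epidermal
2.168184	Hemopexin
-2.212400	Secernin-1
-2.798080	Xaa-Pro dipeptidase
-3.226480	Inter-alpha-trypsin inhibitor heavy chain H1
-2.365450	Protein FAM3C
-1.999030	Adenosylhomocysteinase
-4.444780	Neuropilin-2
-1.820060	Zyxin
-2.953410	Protein S100-A16
-1.856720	Vitamin K-dependent protein S
-1.774900	F-actin-capping protein subunit beta
-1.887960	Proliferating cell nuclear antigen
-4.294040	T-complex protein 1 subunit zeta
-2.264620	Target of Nesh-SH3
-1.679840	Nucleolin
-1.589600	Transforming growth factor-beta
-1.650880	Keratin, type I cytoskeletal 18
-3.273540	Heat shock protein HSP 90-alpha
-2.766990	Plectin
-1.740940	Glypican-1
-2.359940	Endoplasmin
-2.178440	Serglycin
-2.999550	Stathmin
-1.808930	Complement C1r subcomponent
-2.083190	Vinculin
-2.877800	Tubulin beta chain
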