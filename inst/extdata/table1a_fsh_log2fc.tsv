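log2fc	protein
2.462605	Alpha-N-acetylglucosaminidase
1.752348	Microfibril-associated glycoprotein
2.343508	Laminin subunit beta-2
1.645163	Gamma-glutamyl hydrolase
1.798968	Apolipoprotein B-100
2.606067	CD81 antigen
1.694437	Platelet-derived growth factor D
1.656530	Laminin subunit alpha-1
2.022212	Laminin subunit alpha-5
2.619948	Plasma serine protease inhibitor
1.563853	Golgi membrane protein 1
2.426078	Matrilin-2
2.406238	Twisted gastrulation protein homolog 1
1.552728	Nidogen-1
1.784398	Pigment epithelium-derived factor
1.824181	Prothrombin
1.998121	Pleiotrophin
1.537331	Growth arrest-specific protein 6
2.489509	Hemicentin-1
2.567545	Insulin-like growth factor-binding protein 4
1.952312	Collagen alpha-1(V) chain
2.031291	EGF-containing fibulin-like extracellular matrix protein 2
1.808948	CD109 antigen
2.017599	CD59 glycoprotein
1.713896	Complement C1s subcomponent
3.488902	Lysyl oxidase homolog 1
1.802008	Isoform 6 of Agrin
1.880320	Collagen alpha-1(XII) chain
1.787403	Complement factor H
1.951293	Fibulin-2
1.871816	Collagen alpha-2(V) chain
1.548432	Collagen alpha-1(IV) chain
1.932117	Collagen alpha-1(III) chain
2.011173	Basement membrane-specific heparan sulfate proteoglycan core protein
-5.505610	Endoplasmin
-4.374760	Glucose-6-phosphate isomerase
-3.234220	Talin-1
-2.795700	Phosphoglucomutase-1
-3.282750	Rab GDP dissociation inhibitor beta
-5.279550	Elongation factor 1-alpha 1
-4.198640	Filamin-C
-2.318990	Protein S100-A11
-2.326290	Thioredoxin reductase 1
-3.138400	14-3-3 protein theta
-2.982760	Filamin-B
-1.562770	Ribonuclease inhibitor
-1.853380	60S ribosomal protein L10a
-2.004790	Plastin-3
-2.989470	L-lactate dehydrogenase B chain
-2.086530	Neuropilin-2
-2.603040	Protein disulfide-isomerase
-4.626310	Vinculin
-3.093090	Calreticulin
-1.901950	Coactosin-like protein
-1.882610	Heterogeneous nuclear ribonucleoproteins A2/B1
-2.147150	Phosphoglycerate mutase 1
-4.018000	Moesin
-2.658510	Transgelin-2
-2.378480	Ubiquitin carboxyl-terminal hydrolase isozyme L1
-1.738770	Elongation factor 2
-1.519050	Di-N-acetylchitobiase
-1.828800	Endoplasmic reticulum chaperone BiP
-1.516550	Phosphoglycerate kinase 1
-2.038010	Filamin-A
-3.037710	Heat shock cognate 71 kDa protein
-3.492520	Alpha-actinin-1
-1.557200	Peroxiredoxin-1
-2.162680	Pyruvate kinase PKM
-1.905670	Profilin-1
-1.764460	Peptidyl-prolyl cis-trans isomerase A
-2.104610	Cofilin-1
-1.602320	14-3-3 protein zeta/delta
-2.306930	14-3-3 protein epsilon
-2.289490	Fructose-bisphosphate aldolase A
-3.051390	Alpha-enolase
-2.431630	Galectin-1
-2.500070	Vimentin
-2.225750	Keratin, type II cytoskeletal 1
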