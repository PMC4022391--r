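pathway_id	name	es	n_enriched	n_total	kos
ko00240	Pyrimidine metabolism	4.058130678	10	165	K00525;K00526;K00762;K01493;K02323;K02335;K03006;K03465;K10807;K10808
ko03030	DNA replication	2.967323268	4	51	K02314;K02335;K03111;K10755
ko00230	Purine metabolism	2.475427099	10	251	K00525;K00526;K00860;K00939;K01768;K02323;K02335;K03006;K10807;K10808
ko00051	Fructose and mannose metabolism	2.337880458	5	77	K00971;K01623;K01711;K01809;K02377
ko00670	One carbon pool by folate	1.568059864	2	27	K00605;K03465
ko03430	Mismatch repair	1.346727877	2	45	K03111;K10755
ko00540	Lipopolysaccharide biosynthesis	1.215485245	2	34	K00979;K03111
ko00480	Glutathione metabolism	0.930033621	2	39	K10807;K10808
ko00710	Carbon fixation in photosynthetic organisms	0.866466913	2	36	K01623;K01808
ko00520	Amino sugar and nucleotide sugar metabolism	0.740996687	4	129	K00971;K01711;K01809;K02377
ko03420	Nucleotide excision repair	0.699379877	2	48	K02335;K10755
ko00680	Methane metabolism	0.679862658	4	224	K00124;K01079;K01623;K08350
ko03440	Homologous recombination	0.626567452	2	59	K02335;K03111
ko00030	Pentose phosphate pathway	0.547242261	2	57	K01623;K01808
ko00061	Fatty acid biosynthesis	0.533333333	1	30	K02371
ko00195	Photosynthesis	0.528989459	2	63	K02703;K02706
ko00770	Pantothenate and CoA biosynthesis	0.5	1	32	K00606
ko00630	Glyoxylate and dicarboxylate metabolism	0.425930951	2	76	K00124;K08350
ko04113	Meiosis - yeast	0.388260624	2	99	K01768;K02604
ko00260	Glycine, serine and threonine metabolism	0.351753529	2	85	K00605;K01079
ko03060	Protein export	0.256223722	1	39	K03217
ko00521	Streptomycin biosynthesis	0.175276585	1	18	K01710
ko04122	Sulfur relay system	0.163056569	1	21	K11179
ko00910	Nitrogen metabolism	0.162848544	2	117	K00459;K00605
ko04112	Cell cycle - Caulobacter	0.162846923	1	31	K02314
ko00071	Fatty acid metabolism	0.162080418	1	49	K06445
ko03070	Bacterial secretion system	0.135036827	1	74	K03217
ko00010	Glycolysis/Gluconeogenesis	0.133035339	1	91	K01623
ko00190	Oxidative phosphorylation	0.127347781	2	212	K05575;K05580
ko03013	RNA transport	0.119402985	1	134	K03257
ko02020	Two-component system	0.11066639	2	377	K02040;K08350
ko01055	Biosynthesis of vancomycin group antibiotics	0.108792363	1	29	K01710
ko00523	Polyketide sugar unit biosynthesis	0.098593079	1	32	K01710
ko00330	Arginine and proline metabolism	0.091966665	2	131	K00472;K01572
ko00920	Sulfur metabolism	0.085907839	1	34	K00860
ko00270	Cysteine and methionine metabolism	0.075367382	1	70	K00558
ko03410	Base excision repair	0.06057902	1	41	K02335
ko04110	Cell cycle	0.060121472	1	106	K02604
ko05152	Tuberculosis	0.054554001	1	131	K02040
ko04111	Cell cycle - yeast	0.054007424	1	118	K02604
ko05111	Vibrio cholerae pathogenic cycle	0.048892513	1	43	K03087
ko03020	RNA polymerase	0.043861709	1	51	K03006
ko04115	p53 signaling pathway	0.036197553	1	59	K10808
ko00620	Pyruvate metabolism	0.034831078	1	75	K01572
ko04141	Protein processing in endoplasmic reticulum	0.027176857	1	140	K09503
ko03010	Ribosome	0.026398087	1	144	K02963
ko02010	ABC transporters	0.019687532	1	363	K02040
ko05168	Herpes simplex infection	0.017753549	1	126	K03006
ko05016	Huntington's disease	0.015013068	1	149	K03006
ko05169	Epstein-Barr virus infection	0.014912981	1	150	K03006
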