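species	phylum	prevalence_pct	supporting_studies
Faecalibacterium_prausnitzii	Firmicutes	94	Frankel2017,Gopalakrishnan2018,Matson2018,Baruch2021,Davar2021
Roseburia_faecis	Firmicutes	70	Gopalakrishnan2018,Matson2018,Baruch2021,Davar2021
Bacteroides_ovatus	Bacteroidetes	96	Gopalakrishnan2018,Matson2018,Davar2021
Bacteroides_vulgatus	Bacteroidetes	99	Gopalakrishnan2018,Matson2018,Davar2021
Blautia_wexlerae	Firmicutes	80	Frankel2017,Matson2018,Baruch2021
Collinsella_aerofaciens	Actinobacteria	79	Matson2018,Baruch2021,Davar2021
Eubacterium_siraeum	Firmicutes	52	Frankel2017,Gopalakrishnan2018,Matson2018
Roseburia_hominis	Firmicutes	71	Frankel2017,Gopalakrishnan2018,Davar2021
Ruminococcus_bromii	Firmicutes	47	Frankel2017,Gopalakrishnan2018,Davar2021
Acidaminococcus_intestini	Firmicutes	36	Baruch2021,Davar2021
Bifidobacterium_adolescentis	Actinobacteria	47	Matson2018,Baruch2021
Bifidobacterium_longum	Actinobacteria	53	Matson2018,Baruch2021
Eubacterium_rectale	Firmicutes	87	Baruch2021,Davar2021
Fusicatenibacter_saccharivorans	Firmicutes	79	Gopalakrishnan2018,Baruch2021
Parabacteroides_distasonis	Bacteroidetes	96	Gopalakrishnan2018,Davar2021
Parabacteroides_merdae	Bacteroidetes	89	Matson2018,Davar2021
Phascolarctobacterium_faecium	Firmicutes	59	Gopalakrishnan2018,Davar2021
Ruminococcus_bicirculans	Firmicutes	46	Frankel2017,Gopalakrishnan2018
Ruthenibacterium_lactatiformans	Firmicutes	95	Matson2018,Davar2021
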