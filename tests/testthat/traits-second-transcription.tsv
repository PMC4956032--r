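species	femur_length_cm	metaplastic_projections
Velociraptor	18.7	0
Tyrannotitan	140	1
Tyrannosaurus	134.25	1
Troodon	30	0
Torvosaurus	83	1
Struthiomimus	51.3	0
Staurikosaurus	23.5	0
Spinosaurus	61	0
Sinovenator	11.11	0
Sinosauropteryx	8.64	0
Shuvuuia	12.45	0
Shenzhousaurus	19.1	0
Saurornitholestes	22.5	0
Saurornithoides	14	0
Rahonavis	8.8	0
Ornithomimus	50	0
Ornitholestes	21.00	0
Neovenator	75	1
Mononykus	13.84	0
Mirischia	16.5	0
Microvenator	12.4	0
Microraptor	7.59	0
Mei	8.1	0
Masiakasaurus	19.36	0
Majungasaurus	56.80	1
Liliensternus	44.9	0
Khaan	18.8	0
Jinfengopteryx	7.032	0
Huaxiagnathus	16.3	0
Herrerasaurus	35.4	0
Guanlong	41.6	0
Garudimimus	49.9	1
Fukuiraptor	50.7	0
Falcarius	34	0
Eoraptor	15.2	0
Dilophosaurus	58.7	0
Deinonychus	33.6	0
Daspletosaurus	100	1
Compsognathus	11	0
Coelurus	21	0
Coelophysis	21.74	0
Citipati	41.1	0
Chirostenotes	31	0
Ceratosaurus	62	0
Caudipteryx	15.2	0
Carnotaurus	103	1
Buitreraptor	14.5	0
Baryonyx	120	1
Bambiraptor	17	0
Avimimus	18.6	0
Archaeornithomimus	31.4	0
Archaeopteryx	5.8	0
Allosaurus	100.1	1
Albertosaurus	106.6	1
Acrocanthosaurus	127.7	1
Achillobator	50.5	0
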