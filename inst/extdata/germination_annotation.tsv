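gene_id	subgroup	germination_class	protein_function
At2g28470	G1A	promote	BGAL8, beta-galactosidase
At4g26320	G1A	promote	AGP13, arabinogalactan protein
At4g33720	G1A	unknown	CAPE3, cysteine-rich secretory protein
At2g40330	G1A	inhibit	PYL6, ABA receptor component
At2g15370	G1A	unknown	FUT5, fucosyltransferase
At5g42180	G1A	either	PRX64, peroxidase
At1g09090	G1A	promote	RBOHB, respiratory burst oxidase homolog
At4g20460	G1B	promote	NAD(P)-binding Rossmann-fold superfamily
At4g35060	G1B	unknown	HMP39, heavy metal transport/detoxification
At4g40010	G1B	inhibit	SNRK2-7, kinase
At4g17340	G1B	promote	TIP2;2, aquaporin
At1g15380	G1B	either	GLYI4, ABA and JA crosstalk
At2g44790	G1B	inhibit	UCC2, plantacyanin, light-dependent germination
At4g26220	G1B	unknown	Caffeoyl-coenzyme A O-methyltransferase
At1g05260	G1B	either	PER3, cold-inducible cationic peroxidase
At1g78090	G1B	either	Homologous to trehalose-6-phosphate phosphatases
At5g57560	G4A	unknown	XTH22, xyloglucan endotransglucosylase/hydrolase
At5g64100	G4A	inhibit	PRX69, class III peroxidase
At1g51170	G4A	unknown	Protein kinase, interacts with transcription factor ATS
At4g30080	G4A	inhibit	ARF16, AUXIN RESPONSE FACTOR 16
At1g19050	G4A	promote	ARR7, regulator in response to cytokinin
At4g37900	G4A	inhibit	GRDP2, positive auxin signaling
At3g13380	G4A	unknown	BRL3, brassinosteroid receptor
At2g34080	G4A	promote	Cysteine proteinase
At4g03140	G4A	inhibit	NAD(P)-binding Rossmann-fold superfamily
At2g28350	G4A	inhibit	ARF10, AUXIN RESPONSE FACTOR 10
At2g22420	G4A	either	PRX17, cell wall-localized class III peroxidase
At1g23060	G4A	unknown	MDP40, MICROTUBULE DESTABILIZING PROTEIN 40
At1g22880	G4A	promote	CELLULASE 5
At2g23060	G4A	unknown	Acyl-CoA N-acyltransferase
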