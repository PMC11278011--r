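pfam_acc	description
PF00109	beta-ketoacyl synthase N-terminal
PF02801	beta-ketoacyl synthase C-terminal
PF00698	acyl transferase
PF08659	ketoreductase
PF14765	polyketide synthase dehydratase
PF00668	condensation
PF00501	AMP-binding adenylation
PF00550	phosphopantetheine attachment
PF00975	thioesterase
PF07993	NAD-binding reductase
PF11991	tryptophan dimethylallyltransferase
PF06330	trichodiene/terpene synthase
PF00494	squalene/phytoene synthase
PF13243	squalene-hopene cyclase C-terminal
PF13249	squalene-hopene cyclase N-terminal
PF00067	cytochrome P450 monooxygenase
PF01494	FAD-binding monooxygenase
PF00891	O-methyltransferase
PF13649	SAM methyltransferase (Methyltransf_25)
PF08242	SAM methyltransferase (Methyltransf_12)
PF00107	zinc-binding alcohol dehydrogenase
PF03171	2OG-Fe(II) oxygenase
PF04820	tryptophan halogenase
PF00248	aldo/keto reductase
PF05368	NmrA-like reductase
PF01073	3-beta hydroxysteroid dehydrogenase/isomerase
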