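pfam_acc	domain_name	role
PF00109	beta-ketoacyl synthase N-terminal	ks
PF02801	beta-ketoacyl synthase C-terminal	ks
PF00698	acyl transferase	at
PF08659	ketoreductase	pks_extra
PF14765	polyketide synthase dehydratase	pks_extra
PF00668	condensation	c
PF00501	AMP-binding adenylation	a
PF00550	phosphopantetheine attachment (carrier)	carrier
PF00975	thioesterase	te
PF07993	NAD-binding reductase (NRPS terminal)	red
PF11991	tryptophan dimethylallyltransferase	dmats
PF06330	trichodiene/terpene synthase	tc
PF00494	squalene/phytoene synthase	tc
PF13243	squalene-hopene cyclase C-terminal	tc
PF13249	squalene-hopene cyclase N-terminal	tc
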