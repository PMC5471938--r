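# Semantic-group -> semantic-type mapping (reconstructed snapshot of the
# public UMLS Semantic Network grouping; user-replaceable: drop in your own
# table with the same three columns to override).
group_id	group_name	st
ACTI	activities & behaviors	acty
ACTI	activities & behaviors	bhvr
ACTI	activities & behaviors	dora
ACTI	activities & behaviors	evnt
ACTI	activities & behaviors	gora
ACTI	activities & behaviors	inbe
ACTI	activities & behaviors	mcha
ACTI	activities & behaviors	ocac
ACTI	activities & behaviors	socb
ANAT	anatomy	anst
ANAT	anatomy	blor
ANAT	anatomy	bpoc
ANAT	anatomy	bsoj
ANAT	anatomy	bdsu
ANAT	anatomy	bdsy
ANAT	anatomy	celc
ANAT	anatomy	cell
ANAT	anatomy	emst
ANAT	anatomy	ffas
ANAT	anatomy	tisu
CHEM	chemicals & drugs	aapp
CHEM	chemicals & drugs	antb
CHEM	chemicals & drugs	bacs
CHEM	chemicals & drugs	bodm
CHEM	chemicals & drugs	chem
CHEM	chemicals & drugs	chvf
CHEM	chemicals & drugs	chvs
CHEM	chemicals & drugs	clnd
CHEM	chemicals & drugs	elii
CHEM	chemicals & drugs	enzy
CHEM	chemicals & drugs	hops
CHEM	chemicals & drugs	horm
CHEM	chemicals & drugs	imft
CHEM	chemicals & drugs	inch
CHEM	chemicals & drugs	irda
CHEM	chemicals & drugs	nnon
CHEM	chemicals & drugs	orch
CHEM	chemicals & drugs	phsu
CHEM	chemicals & drugs	rcpt
CHEM	chemicals & drugs	vita
CONC	concepts & ideas	clas
CONC	concepts & ideas	cnce
CONC	concepts & ideas	ftcn
CONC	concepts & ideas	grpa
CONC	concepts & ideas	idcn
CONC	concepts & ideas	inpr
CONC	concepts & ideas	lang
CONC	concepts & ideas	qlco
CONC	concepts & ideas	qnco
CONC	concepts & ideas	rnlw
CONC	concepts & ideas	spco
CONC	concepts & ideas	tmco
DEVI	devices	drdd
DEVI	devices	medd
DEVI	devices	resd
DISO	disorders	acab
DISO	disorders	anab
DISO	disorders	cgab
DISO	disorders	comd
DISO	disorders	dsyn
DISO	disorders	emod
DISO	disorders	fndg
DISO	disorders	inpo
DISO	disorders	mobd
DISO	disorders	neop
DISO	disorders	patf
DISO	disorders	sosy
GENE	genes & molecular sequences	amas
GENE	genes & molecular sequences	crbs
GENE	genes & molecular sequences	gngm
GENE	genes & molecular sequences	mosq
GENE	genes & molecular sequences	nusq
GEOG	geographic areas	geoa
LIVB	living beings	aggp
LIVB	living beings	amph
LIVB	living beings	anim
LIVB	living beings	arch
LIVB	living beings	bact
LIVB	living beings	bird
LIVB	living beings	euka
LIVB	living beings	fish
LIVB	living beings	fngs
LIVB	living beings	grup
LIVB	living beings	humn
LIVB	living beings	mamm
LIVB	living beings	orgm
LIVB	living beings	plnt
LIVB	living beings	popg
LIVB	living beings	prog
LIVB	living beings	rept
LIVB	living beings	virs
LIVB	living beings	vtbt
OBJC	objects	enty
OBJC	objects	food
OBJC	objects	mnob
OBJC	objects	sbst
OCCU	occupations	bmod
OCCU	occupations	ocdi
ORGA	organizations	hcro
ORGA	organizations	orgt
ORGA	organizations	pros
ORGA	organizations	shro
PHEN	phenomena	eehu
PHEN	phenomena	hcpp
PHEN	phenomena	lbtr
PHEN	phenomena	npop
PHEN	phenomena	phpr
PHYS	physiology	celf
PHYS	physiology	clna
PHYS	physiology	genf
PHYS	physiology	menp
PHYS	physiology	moft
PHYS	physiology	orgf
PHYS	physiology	orga
PHYS	physiology	ortf
PHYS	physiology	phsf
PROC	procedures	diap
PROC	procedures	edac
PROC	procedures	hlca
PROC	procedures	lbpr
PROC	procedures	mbrt
PROC	procedures	resa
PROC	procedures	topp
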