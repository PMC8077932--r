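generic	brands	family
agomelatine	valdoxan	other
amineptine		tricyclic
amitriptyline	elavil	tricyclic
amoxapine	asendin	tricyclic
bupropion	wellbutrin|zyban	other
butriptyline		tricyclic
citalopram	celexa	SSRI
clomipramine	anafranil	tricyclic
desipramine	norpramin	tricyclic
desvenlafaxine	pristiq	SNRI
dibenzepin		tricyclic
dosulepin	prothiaden	tricyclic
doxepin	sinequan	tricyclic
duloxetine	cymbalta	SNRI
escitalopram	lexapro|cipralex	SSRI
etoperidone		other
fluoxetine	prozac|sarafem	SSRI
fluvoxamine	luvox	SSRI
hydroxynefazodone		other
imipramine	tofranil	tricyclic
iprindole		tricyclic
levomilnacipran	fetzima	SNRI
lofepramine	gamanil	tricyclic
maprotiline	ludiomil	tetracyclic
mazindol		other
meta-chlorophenylpiperazine		other
mianserin	tolvon	tetracyclic
mirtazapine	remeron	tetracyclic
nefazodone	serzone	other
nisoxetine		other
nomifensine	merital	other
norclomipramine		tricyclic
northiaden		tricyclic
nortriptyline	pamelor	tricyclic
opipramol	insidon	tricyclic
oxaprotiline		tetracyclic
paroxetine	paxil|seroxat	SSRI
protriptyline	vivactil	tricyclic
reboxetine	edronax	other
sertraline	zoloft|lustral	SSRI
setiptiline	tecipul	tetracyclic
trazodone	desyrel|oleptro	other
triazoledione		other
trimipramine	surmontil	tricyclic
venlafaxine	effexor	SNRI
vilazodone	viibryd	SSRI
viloxazine	vivalan	other
vortioxetine	trintellix|brintellix	other
zimelidine	zelmid	SSRI
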