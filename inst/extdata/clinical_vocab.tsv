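field	token	value
sex	male	male
sex	m	male
sex	man	male
sex	female	female
sex	f	female
sex	woman	female
smoking	never	never
smoking	never-smoker	never
smoking	nonsmoker	never
smoking	non-smoker	never
smoking	no	never
smoking	ever	ever
smoking	smoker	ever
smoking	former	ever
smoking	ex-smoker	ever
smoking	current	ever
smoking	yes	ever
histology	adeno	adeno
histology	adenocarcinoma	adeno
histology	ade	adeno
histology	ac	adeno
histology	scc	scc
histology	squamous	scc
histology	squamous cell carcinoma	scc
histology	sq	scc
histology	large	large
histology	large cell	large
histology	large cell carcinoma	large
histology	lcc	large
histology	other	other
histology	nos	other
histology	mixed	other
stage	1	1
stage	i	1
stage	ia	1
stage	ib	1
stage	2	2
stage	ii	2
stage	iia	2
stage	iib	2
stage	3	3
stage	iii	3
stage	iiia	3
stage	iiib	3
stage	4	4
stage	iv	4
grade	well	well
grade	1	well
grade	g1	well
grade	well differentiated	well
grade	moderate	moderate
grade	2	moderate
grade	g2	moderate
grade	moderately differentiated	moderate
grade	poor	poor
grade	3	poor
grade	g3	poor
grade	poorly differentiated	poor
margins_negative	1	1
margins_negative	0	0
margins_negative	negative	1
margins_negative	positive	0
margins_negative	yes	1
margins_negative	no	0
chemo	1	1
chemo	0	0
chemo	yes	1
chemo	no	0
radio	1	1
radio	0	0
radio	yes	1
radio	no	0
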