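# minimal PSICQUIC-style MITAB 2.5 export, human interactions
uniprotkb:P62993	uniprotkb:P03372	intact:EBI-401755	intact:EBI-78473	uniprotkb:GRB2(gene name)	uniprotkb:ESR1(gene name)	psi-mi:"MI:0007"	-	pubmed:10788520	taxid:9606(human)	taxid:9606(human)	psi-mi:"MI:0915"	psi-mi:"MI:0469"	intact:EBI-1	-
uniprotkb:P05412	uniprotkb:P05412	intact:EBI-852823	intact:EBI-852823	uniprotkb:JUN(gene name)	uniprotkb:JUN(gene name)	psi-mi:"MI:0018"	-	pubmed:11152613	taxid:9606(human)	taxid:9606(human)	psi-mi:"MI:0915"	psi-mi:"MI:0469"	intact:EBI-2	-
uniprotkb:P62993	uniprotkb:P46108	intact:EBI-401755	intact:EBI-886	uniprotkb:GRB2(gene name)	uniprotkb:CRK(gene name)	psi-mi:"MI:0007"	-	pubmed:10788520	taxid:9606(human)	taxid:9606(human)	psi-mi:"MI:0915"	psi-mi:"MI:0469"	intact:EBI-3	-
uniprotkb:Q62245	uniprotkb:P46108	intact:EBI-397	intact:EBI-886	uniprotkb:Sos1(gene name)	uniprotkb:CRK(gene name)	psi-mi:"MI:0007"	-	pubmed:9879991	taxid:10090(mouse)	taxid:9606(human)	psi-mi:"MI:0915"	psi-mi:"MI:0469"	intact:EBI-4	-
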