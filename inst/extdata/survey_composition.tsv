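class	order	family	genera	species
Oligohymenophorea	Pleuronematida	Pleuronematidae	1	1
Oligohymenophorea	Pleuronematida	Cyclidiidae	2	10
Oligohymenophorea	Sessilida	Scyphidiidae	1	1
Oligohymenophorea	Sessilida	Operculariidae	1	2
Oligohymenophorea	Sessilida	Epistylididae	1	3
Oligohymenophorea	Sessilida	Vorticellidae	3	13
Oligohymenophorea	Ophryoglenida	Ophryoglenidae	1	2
Oligohymenophorea	Philasterida	Cohnilembidae	1	2
Oligohymenophorea	Philasterida	Uronematidae	1	1
Oligohymenophorea	Philasterida	Loxocephalidae	1	2
Oligohymenophorea	Philasterida	Cinetochilidae	2	4
Oligohymenophorea	Tetrahymenida	Glaucomidae	3	6
Oligohymenophorea	Tetrahymenida	Tetrahymenidae	1	1
Oligohymenophorea	Tetrahymenida	Turaniellidae	1	2
Oligohymenophorea	Peniculida	Lembadionidae	1	1
Oligohymenophorea	Peniculida	Frontoniidae	1	2
Oligohymenophorea	Peniculida	Parameciidae	1	1
Karyorelictea	Loxodida	Loxodidae	1	2
Karyorelictea	Protostomatida	Trachelocercidea	1	1
Nassophorea	Synhymeniida	Scaphidiodontidae	1	2
Nassophorea	Nassulida	Nassulidae	1	3
Nassophorea	Nassulida	Furgasoniidae	1	2
Nassophorea	Microthoracida	Leptopharyngidae	1	2
Litostomatea	Pleurostomatida	Amphileptidae	1	1
Litostomatea	Pleurostomatida	Litonotidae	2	7
Litostomatea	Haptorida	Spathidiidae	2	16
Litostomatea	Haptorida	Trachelophyllidae	2	5
Litostomatea	Haptorida	Actinobolinidae	1	1
Litostomatea	Haptorida	Enchelyidae	2	2
Litostomatea	Haptorida	Tracheliidae	3	7
Litostomatea	Haptorida	Lacrymariidae	1	2
Litostomatea	Haptorida	Didiniidae	1	1
Litostomatea	Haptorida	Acropisthiidae	1	1
Litostomatea	Entodiniomorphida	Ophryoscolecidae	1	2
Litostomatea	Cyclotrichiida	Mesodiniidae	1	1
Armophorea	Armophorida	Metopidae	1	2
Prostomatea	Prorodontida	Colepidae	1	1
Prostomatea	Prorodontida	Holophryidae	1	4
Prostomatea	Prorodontida	Prorodontidae	2	5
Prostomatea	Prorodontida	Urotrichidae	1	4
Prostomatea	Prorodontida	Plagiocampidae	1	3
Prostomatea	Prorodontida	Placidae	1	1
Colpodea	Cyrtolophosidida	Cyrtolophosididae	1	4
Colpodea	Cyrtolophosidida	Platyophryidae	1	2
Colpodea	Colpodida	Colpodidae	2	6
Colpodea	Colpodida	Grossglockneriidae	1	1
Colpodea	Bryophryida	Bryophyidea	1	1
Plagiopylea	Plagiopylida	Plagiopylidae	1	1
Plagiopylea	Odontostomatida	Epalxellidae	1	1
Spirotrichea	Strombidiida	Strombidiidae	1	1
Spirotrichea	Stichotrichida	Spirofilidae	1	2
Spirotrichea	Stichotrichida	Keronidae	1	1
Spirotrichea	Sporadotrichida	Halteriidae	1	1
Spirotrichea	Sporadotrichida	Trachelostylidae	1	1
Spirotrichea	Sporadotrichida	Oxytrichidae	7	15
Spirotrichea	Urostylida	Urostylidae	4	8
Spirotrichea	Euplotida	Euplotidae	1	4
Spirotrichea	Euplotida	Aspidiscidae	1	1
Spirotrichea	Choreotrichida	Strobilidiidae	1	2
Phyllopharyngea	Endogenida	Acinetidae	1	1
Phyllopharyngea	Exogenida	Podophryidae	1	3
Phyllopharyngea	Chlamydodontida	Chilodonellidae	1	6
Heterotrichea	Heterotrichida	Blepharismidae	1	2
Heterotrichea	Heterotrichida	Stentoridae	1	1
Heterotrichea	Heterotrichida	Spirostomidae	1	1
Heterotrichea	Heterotrichida	Condylostomatidae	1	1
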