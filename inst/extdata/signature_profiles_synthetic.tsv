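channel	brca_like	age_like	apobec_like
A[C>A]A	0.0010593565313539	0.00292397660818713	0.00100806451612903
A[C>A]C	9.3519250613317e-06	0.00292397660818713	0.00100806451612903
A[C>A]G	0.0176369450261512	0.00292397660818713	0.00100806451612903
A[C>A]T	0.000155697712067338	0.00292397660818713	0.00100806451612903
C[C>A]A	1.37448846764897e-06	0.00292397660818713	0.00100806451612903
C[C>A]C	0.00259216978151786	0.00292397660818713	0.00100806451612903
C[C>A]G	2.28834927859667e-05	0.00292397660818713	0.00100806451612903
C[C>A]T	0.0431563449905308	0.00292397660818713	0.00100806451612903
G[C>A]A	0.000380981182753093	0.00292397660818713	0.00100806451612903
G[C>A]C	3.36327512544895e-06	0.00292397660818713	0.00100806451612903
G[C>A]G	0.00634285434350113	0.00292397660818713	0.00100806451612903
G[C>A]T	5.59942726926452e-05	0.00292397660818713	0.00100806451612903
T[C>A]A	0.105600494313507	0.00292397660818713	0.00100806451612903
T[C>A]C	0.000932233747591429	0.00292397660818713	0.00100806451612903
T[C>A]G	8.2296940539719e-06	0.00292397660818713	0.00100806451612903
T[C>A]T	0.015520511623013	0.00292397660818713	0.00100806451612903
A[C>G]A	0.000137013986619257	0.00292397660818713	0.00100806451612903
A[C>G]C	1.20954985153109e-06	0.00292397660818713	0.00100806451612903
A[C>G]G	0.00228110940773572	0.00292397660818713	0.00100806451612903
A[C>G]T	2.01374736516507e-05	0.00292397660818713	0.00100806451612903
C[C>G]A	0.0379775835916671	0.00292397660818713	0.00100806451612903
C[C>G]C	0.000335263440822722	0.00292397660818713	0.00100806451612903
C[C>G]G	2.95968211039508e-06	0.00292397660818713	0.00100806451612903
C[C>G]T	0.00558171182228099	0.00292397660818713	0.00100806451612903
G[C>G]A	4.92749599695278e-05	0.00292397660818713	0.00100806451612903
G[C>G]C	0.0929284349958861	0.00292397660818713	0.00100806451612903
G[C>G]G	0.000820365697880458	0.00292397660818713	0.00100806451612903
G[C>G]T	7.24213076749527e-06	0.00292397660818713	0.00100806451612903
T[C>G]A	0.0136580502282515	0.00292397660818713	0.201612903225806
T[C>G]C	0.000120572308224946	0.00292397660818713	0.00100806451612903
T[C>G]G	1.06440386934736e-06	0.00292397660818713	0.00100806451612903
T[C>G]T	0.00200737627880743	0.00292397660818713	0.201612903225806
A[C>T]A	1.77209768134526e-05	0.00292397660818713	0.00100806451612903
A[C>T]C	0.033420273560667	0.00292397660818713	0.00100806451612903
A[C>T]G	0.000295031827923995	0.182748538011696	0.00100806451612903
A[C>T]T	2.60452025714767e-06	0.00292397660818713	0.00100806451612903
C[C>T]A	0.00491190640360727	0.00292397660818713	0.00100806451612903
C[C>T]C	4.33619647731844e-05	0.00292397660818713	0.00100806451612903
C[C>T]G	0.0817770227963797	0.182748538011696	0.00100806451612903
C[C>T]T	0.000721921814134803	0.00292397660818713	0.00100806451612903
G[C>T]A	6.37307507539584e-06	0.00292397660818713	0.00100806451612903
G[C>T]C	0.0120190842008613	0.00292397660818713	0.00100806451612903
G[C>T]G	0.000106103631237953	0.182748538011696	0.00100806451612903
G[C>T]T	9.36675405025677e-07	0.00292397660818713	0.00100806451612903
T[C>T]A	0.00176649112535054	0.00292397660818713	0.252016129032258
T[C>T]C	1.55944595958383e-05	0.00292397660818713	0.00100806451612903
T[C>T]G	0.029409840733387	0.182748538011696	0.00100806451612903
T[C>T]T	0.000259628008573116	0.00292397660818713	0.252016129032258
A[T>A]A	2.29197782628995e-06	0.00292397660818713	0.00100806451612903
A[T>A]C	0.0043224776351744	0.00292397660818713	0.00100806451612903
A[T>A]G	3.81585290004023e-05	0.00292397660818713	0.00100806451612903
A[T>A]T	0.0719637800608142	0.00292397660818713	0.00100806451612903
C[T>A]A	0.000635291196438627	0.00292397660818713	0.00100806451612903
C[T>A]C	5.60830606634834e-06	0.00292397660818713	0.00100806451612903
C[T>A]G	0.0105767940967579	0.00292397660818713	0.00100806451612903
C[T>A]T	9.33711954893985e-05	0.00292397660818713	0.00100806451612903
G[T>A]A	8.24274356422596e-07	0.00292397660818713	0.00100806451612903
G[T>A]C	0.00155451219030848	0.00292397660818713	0.00100806451612903
G[T>A]G	1.37231244443377e-05	0.00292397660818713	0.00100806451612903
G[T>A]T	0.0258806598453806	0.00292397660818713	0.00100806451612903
T[T>A]A	0.000228472647544342	0.00292397660818713	0.00100806451612903
T[T>A]C	2.01694048713515e-06	0.00292397660818713	0.00100806451612903
T[T>A]G	0.00380378031895347	0.00292397660818713	0.00100806451612903
T[T>A]T	3.3579505520354e-05	0.00292397660818713	0.00100806451612903
A[T>C]A	0.0633281264535165	0.00292397660818713	0.00100806451612903
A[T>C]C	0.000559056252865991	0.00292397660818713	0.00100806451612903
A[T>C]G	4.93530933838654e-06	0.00292397660818713	0.00100806451612903
A[T>C]T	0.00930757880514699	0.00292397660818713	0.00100806451612903
C[T>C]A	8.21666520306706e-05	0.00292397660818713	0.00100806451612903
C[T>C]C	7.25361433651884e-07	0.00292397660818713	0.00100806451612903
C[T>C]G	0.00136797072747146	0.00292397660818713	0.00100806451612903
C[T>C]T	1.20763495110172e-05	0.00292397660818713	0.00100806451612903
G[T>C]A	0.0227749806639349	0.00292397660818713	0.00100806451612903
G[T>C]C	0.000201055929839021	0.00292397660818713	0.00100806451612903
G[T>C]G	1.77490762867893e-06	0.00292397660818713	0.00100806451612903
G[T>C]T	0.00334732668067906	0.00292397660818713	0.00100806451612903
T[T>C]A	2.95499648579115e-05	0.00292397660818713	0.00100806451612903
T[T>C]C	0.0557287512790945	0.00292397660818713	0.00100806451612903
T[T>C]G	0.000491969502522072	0.00292397660818713	0.00100806451612903
T[T>C]T	4.34307221778015e-06	0.00292397660818713	0.00100806451612903
A[T>G]A	0.00819066934852935	0.00292397660818713	0.00100806451612903
A[T>G]C	7.23066537869902e-05	0.00292397660818713	0.00100806451612903
A[T>G]G	6.38318061613658e-07	0.00292397660818713	0.00100806451612903
A[T>G]T	0.00120381424017488	0.00292397660818713	0.00100806451612903
C[T>G]A	1.06271875696951e-05	0.00292397660818713	0.00100806451612903
C[T>G]C	0.0200419829842627	0.00292397660818713	0.00100806451612903
C[T>G]G	0.000176929218258338	0.00292397660818713	0.00100806451612903
C[T>G]T	1.56191871323746e-06	0.00292397660818713	0.00100806451612903
G[T>G]A	0.00294564747899757	0.00292397660818713	0.00100806451612903
G[T>G]C	2.60039690749622e-05	0.00292397660818713	0.00100806451612903
G[T>G]G	0.0490413011256032	0.00292397660818713	0.00100806451612903
G[T>G]T	0.000432933162219424	0.00292397660818713	0.00100806451612903
T[T>G]A	3.82190355164653e-06	0.00292397660818713	0.00100806451612903
T[T>G]C	0.00720778902670583	0.00292397660818713	0.00100806451612903
T[T>G]G	6.36298553325513e-05	0.00292397660818713	0.00100806451612903
T[T>G]T	0.120000561719894	0.00292397660818713	0.00100806451612903
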