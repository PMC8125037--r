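chrom	pos	ref	alt	gene	consequence	cadd_phred	ac_case	rsid	transcript	nt_change	aa_change	af_frex	af_nc_nwe	af_popmax
1	9715647	A	G	PIK3CD	missense	25	1	.	NM_005026	c.A248G	p.E83G	.	.	.
1	9715709	C	T	PIK3CD	missense	35	1	.	NM_005026	c.C310T	p.R104C	.	3e-05	9e-06
1	11130641	G	A	MTOR	missense	22.8	2	rs142403193	NM_004958	c.C5501T	p.T1834M	.	9e-04	7e-04
1	11238522	G	A	MTOR	missense	28.9	1	rs751242124	NM_004958	c.C1882T	p.R628C	.	.	5e-05
1	11248030	T	A	MTOR	missense	23.1	1	rs761323069	NM_004958	c.A905T	p.D302V	.	.	3e-04
20	57365381	C	T	RAE1	missense	31	1	rs755561880	NM_003610	c.C314T	p.S105L	.	.	6e-05
20	57365432	A	G	RAE1	missense	20.6	1	.	NM_003610	c.A365G	p.Q122R	.	.	.
21	41991340	G	A	ZBTB21	missense	25.3	1	rs368359632	NM_001098402	c.C2756T	p.T919M	.	.	7e-04
21	41992058	G	A	ZBTB21	missense	26.5	1	rs371004245	NM_001098402	c.C2038T	p.R680C	.	1e-04	1e-04
21	41992762	C	T	ZBTB21	missense	30	1	.	NM_001098402	c.G1334A	p.R445H	.	5e-05	4e-05
11	124753942	G	A	ESAM	missense	34	1	rs760488150	NM_138961	c.C877T	p.R293W	.	5e-05	3e-05
11	124754658	G	A	ESAM	missense	33	1	rs200924772	NM_138961	c.C713T	p.T238M	9e-04	8e-05	2e-04
4	165103020	T	G	TMEM192	missense	22.9	1	.	NM_001100389	c.A104C	p.Q35P	.	.	.
4	165103021	G	A	TMEM192	stopgain	35	1	.	NM_001100389	c.C103T	p.Q35X	.	.	.
22	19210459	C	T	CLTCL1	missense	32	1	rs781878409	NM_007098	c.G3116A	p.R1039Q	.	.	1e-03
22	19219929	C	T	CLTCL1	missense	25.5	1	rs188611399	NM_007098	c.G2875A	p.V959I	.	2e-04	1e-03
22	19224006	T	G	CLTCL1	missense	29.5	1	rs782728804	NM_007098	c.A2177C	p.D726A	.	.	9e-06
22	19226346	T	C	CLTCL1	missense	25.5	1	rs201280856	NM_007098	c.A1820G	p.H607R	.	3e-04	4e-04
22	19233264	C	A	CLTCL1	missense	23.6	1	rs782774942	NM_007098	c.G1423T	p.A475S	.	.	6e-05
22	19234672	A	G	CLTCL1	missense	25.3	1	.	NM_007098	c.T1004C	p.V335A	.	.	.
11	129872957	G	A	NFRKB	missense	31	1	.	NM_006165	c.C2765T	p.P922L	.	.	.
11	129874521	G	A	NFRKB	missense	23.9	1	rs200192480	NM_006165	c.C2113T	p.P705S	.	.	4e-05
11	129884816	G	A	NFRKB	missense	22.9	1	rs755726394	NM_006165	c.C746T	p.A249V	.	.	6e-05
22	41117808	C	T	EP300	missense	21.3	1	.	NM_001429	c.C716T	p.P239L	.	.	.
22	41137724	C	T	EP300	missense	24.9	1	.	NM_001429	c.C1694T	p.T565I	.	.	.
22	41149147	C	T	EP300	missense	23.2	1	rs201480900	NM_001429	c.C2351T	p.P784L	.	8e-05	2e-04
16	70663765	G	A	MTSS2	missense	24.5	1	rs749003640	NM_138383	c.C2156T	p.P719L	.	2e-04	1e-03
16	70664615	T	C	MTSS2	missense	23.9	1	rs147433916	NM_138383	c.A1454G	p.D485G	2e-03	2e-04	2e-03
16	70665044	C	T	MTSS2	missense	26.1	1	rs549028223	NM_138383	c.G1181A	p.R394Q	.	5e-05	2e-03
16	70679820	C	G	MTSS2	missense	29.1	1	rs768341867	NM_138383	c.G348C	p.K116N	.	.	9e-06
3	47046509	C	T	SETD2	missense	33	1	rs766193321	NM_001349370	c.G6944A	p.G2315E	.	3e-05	9e-06
3	47046543	G	T	SETD2	missense	25.9	1	.	NM_001349370	c.C6910A	p.P2304T	.	.	.
3	47084114	A	G	SETD2	missense	25.3	1	rs148097513	NM_001349370	c.T5534C	p.M1845T	9e-04	1e-03	2e-03
3	47121407	T	C	SETD2	missense	23.6	1	rs114719990	NM_001349370	c.A3097G	p.T1033A	2e-03	2e-03	2e-03
3	47123308	C	G	SETD2	missense	25.8	1	.	NM_001349370	c.G1196C	p.R399T	.	.	.
9	104114033	C	T	SMC2	missense	20.6	1	.	NM_001042550	c.C1484T	p.T495I	.	.	.
9	104125007	G	A	SMC2	missense	23	2	rs147960477	NM_001042550	c.G2353A	p.A785T	9e-04	2e-04	9e-04
9	104139220	A	G	SMC2	missense	23.9	1	.	NM_001042550	c.A3499G	p.T1167A	.	.	.
20	2706020	G	A	EBF4	missense	21	1	rs202097996	NM_001110514	c.G329A	p.R110Q	9e-04	6e-05	1e-04
20	2706211	C	A	EBF4	missense	23.3	1	.	NM_001110514	c.C349A	p.L117M	.	.	.
20	2755749	G	A	EBF4	missense	32	1	rs369331115	NM_001110514	c.G1651A	p.A551T	.	.	.
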