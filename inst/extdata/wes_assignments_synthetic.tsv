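case_id	gene	aa_change
W01	PIK3CD	p.E83G
W02	PIK3CD	p.R104C
W03	MTOR	p.T1834M
W04	MTOR	p.T1834M
W05	MTOR	p.R628C
W06	MTOR	p.D302V
W07	RAE1	p.S105L
W08	RAE1	p.Q122R
W09	ZBTB21	p.T919M
W10	ZBTB21	p.R680C
W11	ZBTB21	p.R445H
W12	ESAM	p.R293W
W13	ESAM	p.T238M
W14	TMEM192	p.Q35P
W15	TMEM192	p.Q35X
W16	CLTCL1	p.R1039Q
W17	CLTCL1	p.V959I
W18	CLTCL1	p.D726A
W19	CLTCL1	p.H607R
W20	CLTCL1	p.A475S
W21	CLTCL1	p.V335A
W22	NFRKB	p.P922L
W23	NFRKB	p.P705S
W24	NFRKB	p.A249V
W25	EP300	p.P239L
W26	EP300	p.T565I
W27	EP300	p.P784L
W28	MTSS2	p.P719L
W29	MTSS2	p.D485G
W30	MTSS2	p.R394Q
W31	MTSS2	p.K116N
W16	SETD2	p.G2315E
W17	SETD2	p.P2304T
W18	SETD2	p.M1845T
W32	SETD2	p.T1033A
W33	SETD2	p.R399T
W09	SMC2	p.T495I
W10	SMC2	p.A785T
W12	SMC2	p.A785T
W14	SMC2	p.T1167A
W25	EBF4	p.R110Q
W28	EBF4	p.L117M
W29	EBF4	p.A551T
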