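case_id,sex,age_first_melanoma,age_first_rcc,melanoma_histology,rcc_histology,other_solid_tumors,family_history,mc1r_variants
W01,M,44,47,SSM,ccRCC,TRUE,FALSE,V60L:r
W02,F,39,52,SSM,ccRCC,FALSE,FALSE,R151C:R
W03,M,46,48,SSM,pRCC,TRUE,FALSE,
W04,M,48,50,NM,ccRCC,FALSE,TRUE,R160W:R
W05,F,42,45,SSM,ccRCC,TRUE,FALSE,V92M:r
W06,M,47,49,SSM,ccRCC,FALSE,FALSE,V60L:r;R151C:R
W07,F,51,54,SSM,ccRCC,TRUE,FALSE,
W08,M,53,56,NM,chRCC,FALSE,FALSE,R163Q:r
W09,M,50,55,SSM,ccRCC,TRUE,FALSE,V60L:r
W10,F,54,57,SSM,ccRCC,FALSE,FALSE,
W11,M,52,58,SSM,pRCC,FALSE,TRUE,R160W:R
W12,F,49,53,NM,ccRCC,FALSE,FALSE,V92M:r
W13,M,55,59,SSM,ccRCC,FALSE,FALSE,
W14,M,53,56,SSM,ccRCC,FALSE,FALSE,V60L:r
W15,F,51,54,SSM,chRCC,FALSE,FALSE,R151C:R
W16,M,52,55,SSM,ccRCC,TRUE,FALSE,V60L:r
W17,F,56,58,NM,pRCC,TRUE,FALSE,
W18,M,54,57,SSM,ccRCC,TRUE,TRUE,R163Q:r
W19,M,57,60,SSM,ccRCC,TRUE,FALSE,V92M:r
W20,F,53,56,SSM,ccRCC,FALSE,FALSE,
W21,M,55,58,NM,ccRCC,FALSE,FALSE,V60L:r
W22,F,45,47,SSM,ccRCC,TRUE,FALSE,R160W:R
W23,M,47,50,SSM,ccRCC,FALSE,FALSE,
W24,M,44,46,SSM,pRCC,FALSE,FALSE,V60L:r
W25,F,46,49,SSM,ccRCC,TRUE,FALSE,R151C:R
W26,M,49,51,NM,ccRCC,FALSE,FALSE,
W27,M,43,46,SSM,ccRCC,FALSE,TRUE,V92M:r
W28,F,52,56,SSM,ccRCC,FALSE,FALSE,V60L:r
W29,M,54,58,SSM,chRCC,FALSE,FALSE,
W30,F,50,53,SSM,ccRCC,FALSE,FALSE,R163Q:r
W31,M,56,59,NM,ccRCC,FALSE,FALSE,V60L:r
W32,F,53,55,SSM,ccRCC,TRUE,FALSE,
W33,M,55,58,SSM,pRCC,TRUE,FALSE,R160W:R
W34,M,57,60,SSM,ccRCC,TRUE,FALSE,V60L:r
W35,F,54,57,SSM,ccRCC,TRUE,FALSE,
W36,M,56,59,NM,ccRCC,TRUE,FALSE,R151C:R
W37,F,52,55,SSM,ccRCC,TRUE,FALSE,V60L:r
W38,M,58,61,SSM,ccRCC,FALSE,FALSE,
W39,F,55,58,SSM,pRCC,FALSE,FALSE,V92M:r
W40,M,57,60,SSM,ccRCC,FALSE,TRUE,
W41,M,53,57,NM,ccRCC,FALSE,FALSE,V60L:r
W42,F,56,59,SSM,ccRCC,FALSE,FALSE,R163Q:r
W43,M,58,62,SSM,ccRCC,FALSE,FALSE,
W44,F,54,56,SSM,chRCC,FALSE,FALSE,V60L:r
W45,M,59,63,SSM,ccRCC,FALSE,FALSE,
W46,F,57,61,NM,ccRCC,FALSE,FALSE,R151C:R
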