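case_id,gene,nucleotide_change,aa_change,mc1r_variants,sex,age_first_melanoma,n_melanoma,melanoma_histology,age_first_rcc,rcc_histology,other_solid_tumors,family_history
C01,MITF,c.952G>A,p.E318K,R163Q:r,M,33,2,SSM,27,chRCC,FALSE,TRUE
C02,MITF,c.952G>A,p.E318K,V92M:r,M,37,1,SSM,55,ccRCC,FALSE,FALSE
C03,MITF,c.952G>A,p.E318K,V60L:r;R160W:R,M,62,1,NM,51,ccRCC,FALSE,FALSE
C04,MITF,c.952G>A,p.E318K,,M,52,1,SSM,52,ccRCC,FALSE,TRUE
C05,MITF,c.952G>A,p.E318K,R160W:R;D294H:R,F,56,2,SSM,59,ccRCC,TRUE,TRUE
C06,MITF,c.952G>A,p.E318K,R163Q:r,M,60,1,SSM,60,chRCC,TRUE,TRUE
C07,MITF,c.952G>A,p.E318K,V60L:r,M,69,1,NM,69,ccRCC,FALSE,FALSE
C08,MITF,c.952G>A,p.E318K,R160W:R,M,75,2,NM,70,ccRCC,FALSE,FALSE
C09,MITF,c.952G>A,p.E318K,V92M:r;R151C:R,M,74,3,SSM,74,pRCC,TRUE,TRUE
C10,BAP1,c.37+1delG,p.?,V60L:r;R160W:R,F,29,6,SSM,49,ccRCC,FALSE,TRUE
C11,BAP1,c.78-79del,p.V27fs,,M,45,1,NM,53,ccRCC,FALSE,TRUE
C12,BAP1,c.1938T>A,p.Y646*,V60L:r,F,48,1,SSM,59,ccRCC,TRUE,TRUE
C13,CDKN2A,c.146T>G,p.I49S,V92M:r;R151C:R,F,31,1,SSM,36,ccRCC,FALSE,TRUE
C14,CDKN2A,c.159G>C,p.M53I,V60L:r;R151C:R,M,46,1,NM,61,ccRCC,FALSE,TRUE
C15,FLCN,c.663dupG,p.M222fs,,F,48,1,NM,43,chRCC,TRUE,TRUE
C16,FLCN,c.755dupC,p.C253fs,,M,64,1,SSM,62,ccRCC,TRUE,FALSE
C17,PTEN,c.959T>G,p.L320*,,F,55,1,SSM,55,ccRCC,FALSE,TRUE
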