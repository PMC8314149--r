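center_id,scheme_id,year,outcome,capa_documented
C1,EQA-001,2021,satisfactory,1
C1,EQA-006,2021,satisfactory,1
C1,EQA-004,2022,satisfactory,1
C1,EQA-005,2022,satisfactory,1
C1,EQA-006,2022,clerical_error,0
C1,EQA-002,2023,genotyping_error,1
C1,EQA-006,2023,satisfactory,1
C1,EQA-007,2023,satisfactory,1
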