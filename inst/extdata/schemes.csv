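scheme_id,provider,indication,techniques,scope_technique,scope_genotyping,scope_interpretation,modality,fee_eur,offered_years
EQA-001,EMQN,cystic fibrosis,sequencing;mlpa,1,1,1,wet,1200,
EQA-002,GenQA,cystic fibrosis,sequencing;mlpa,1,1,1,wet,950,
EQA-003,EMQN,huntington disease,fragment_analysis,1,1,1,wet,800,
EQA-004,GenQA,fragile x syndrome,fragment_analysis,1,1,0,wet,700,
EQA-005,EMQN,spinal muscular atrophy,mlpa,1,1,1,wet,900,
EQA-006,GenQA,constitutional karyotype,karyotyping,1,0,0,virtual,400,
EQA-007,EMQN,fragile x syndrome,fragment_analysis,0,0,1,virtual,300,
EQA-008,CAP,spinal muscular atrophy,mlpa,1,1,0,wet,850,
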