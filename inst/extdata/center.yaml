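center_id: C1
techniques:
- technique_id: sequencing
  validation_date: '2015-06-01'
  method_class: in_house
  annual_volume: 450
  exemption_documented: yes
- technique_id: mlpa
  validation_date: '2018-03-15'
  method_class: ce_kit
  annual_volume: 120
  exemption_documented: yes
- technique_id: fragment_analysis
  validation_date: '2021-09-01'
  method_class: in_house
  annual_volume: 350
  exemption_documented: yes
- technique_id: karyotyping
  validation_date: '2010-01-20'
  method_class: in_house
  annual_volume: 800
  last_method_change: '2022-05-10'
  exemption_documented: yes
indications:
- indication: cystic fibrosis
  techniques_used: [sequencing, mlpa]
  annual_requests: 180
- indication: fragile x syndrome
  techniques_used: [fragment_analysis]
  annual_requests: 60
- indication: spinal muscular atrophy
  techniques_used: [mlpa]
  annual_requests: 45
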