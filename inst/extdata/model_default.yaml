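pools:
- name: liver_free
  organ_group: liver
  initial_amount: 4.0
- name: liver_ester
  organ_group: liver
  initial_amount: 2.5
- name: intestine_free
  organ_group: intestine
  initial_amount: 2.0
- name: intestine_ester
  organ_group: intestine
  initial_amount: 0.80000000000000004
- name: periphery
  organ_group: periphery
  initial_amount: 30.0
- name: plasma_hdl_free
  organ_group: plasma
  initial_amount: 1.5
- name: plasma_hdl_ester
  organ_group: plasma
  initial_amount: 3.5
- name: plasma_ldl
  organ_group: plasma
  initial_amount: 10.0
rates:
- id: 1
  process: hepatic cholesterol synthesis
  source: EXTERNAL
  target: liver_free
  law: zero_order
  k: 0.90000000000000002
  genes: DHCR7
- id: 2
  process: peripheral cholesterol synthesis
  source: EXTERNAL
  target: periphery
  law: zero_order
  k: 0.55000000000000004
  genes: DHCR7
- id: 3
  process: intestinal cholesterol synthesis
  source: EXTERNAL
  target: intestine_free
  law: zero_order
  k: 0.34999999999999998
  genes: DHCR7
- id: 4
  process: dietary cholesterol intake
  source: EXTERNAL
  target: intestine_free
  law: zero_order
  k: 0.69999999999999996
  genes: NPC1L1
- id: 5
  process: hepatic uptake of cholesterol from LDL
  source: plasma_ldl
  target: liver_free
  law: first_order_in_source
  k: 0.16
  genes: LDLR,APOB,APOE
- id: 6
  process: VLDL-C secretion
  source: liver_ester
  target: plasma_ldl
  law: first_order_in_source
  k: 0.5
  genes: MTTP
- id: 7
  process: peripheral uptake of cholesterol from LDL
  source: plasma_ldl
  target: periphery
  law: first_order_in_source
  k: 0.10000000000000001
  genes: LDLR,APOB,APOE
- id: 8
  process: peripheral cholesterol transport to HDL
  source: periphery
  target: plasma_hdl_free
  law: first_order_in_source
  k: 0.04333333333333333
  genes: ABCA1
- id: 9
  process: HDL-associated cholesterol esterification
  source: plasma_hdl_free
  target: plasma_hdl_ester
  law: first_order_in_source
  k: 1.19999999999999996
  genes: LCAT
- id: 10
  process: hepatic HDL-CE uptake
  source: plasma_hdl_ester
  target: liver_free
  law: first_order_in_source
  k: 0.25714285714285717
  genes: SCARB1
- id: 11
  process: intestinal chylomicron cholesterol secretion
  source: intestine_ester
  target: plasma_ldl
  law: first_order_in_source
  k: 0.5625
  genes: MTTP
- id: 12
  process: peripheral cholesterol loss
  source: periphery
  target: EXTERNAL
  law: first_order_in_source
  k: 0.00833333333333333
  genes: ''
- id: 13
  process: hepatic HDL-FC uptake
  source: plasma_hdl_free
  target: liver_free
  law: first_order_in_source
  k: 0.19999999999999998
  genes: MTTP
- id: 14
  process: biliary cholesterol excretion
  source: liver_free
  target: intestine_free
  law: first_order_in_source
  k: 0.27500000000000002
  genes: ABCG8,NPC1L1
- id: 15
  process: fecal cholesterol excretion
  source: intestine_free
  target: EXTERNAL
  law: first_order_in_source
  k: 0.69999999999999996
  genes: ''
- id: 16
  process: intestinal cholesterol transport to HDL
  source: intestine_free
  target: plasma_hdl_free
  law: first_order_in_source
  k: 0.14999999999999999
  genes: ABCA1
- id: 17
  process: hepatic cholesterol transport to HDL
  source: liver_free
  target: plasma_hdl_free
  law: first_order_in_source
  k: 0.125
  genes: ABCA1
- id: 18
  process: hepatic cholesterol catabolism
  source: liver_free
  target: EXTERNAL
  law: first_order_in_source
  k: 0.21249999999999999
  genes: CYP7A1
- id: 19
  process: hepatic cholesterol esterification
  source: liver_free
  target: liver_ester
  law: first_order_in_source
  k: 0.3125
  genes: SOAT2
- id: 20
  process: intestinal cholesterol esterification
  source: intestine_free
  target: intestine_ester
  law: first_order_in_source
  k: 0.22500000000000001
  genes: SOAT2
- id: 21
  process: CE transfer from HDL to LDL
  source: plasma_hdl_ester
  target: plasma_ldl
  law: mass_action
  k: 0.02571428571428571
  genes: CETP
gene_map:
  LDLR:
  - 5
  - 7
  APOB:
  - 5
  - 7
  APOE:
  - 5
  - 7
  ABCA1:
  - 8
  - 16
  - 17
  LCAT: 9
  CETP: 21
  CYP7A1: 18
  DHCR7:
  - 1
  - 2
  - 3
  NPC1L1:
  - 4
  - 14
  MTTP:
  - 6
  - 11
  - 13
  SCARB1: 10
  ABCG8: 14
  SOAT2:
  - 19
  - 20
physiology:
  body_weight_kg: 70.0
  organ_volumes_l:
    plasma: 3.0
    liver: 1.80000000000000004
    intestine: 1.19999999999999996
    periphery: 40.0

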