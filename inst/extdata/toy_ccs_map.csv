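icd9_code,ccs_level1,ccs_level2,ccs_level3,ccs_level4
530.11,9,9.4,9.4.1,9.4.1.1
530.12,9,9.4,9.4.1,9.4.1.2
530.81,9,9.4,9.4.2,9.4.2.1
531.00,9,9.5,9.5.1,9.5.1.1
531.10,9,9.5,9.5.1,
578.0,9,9.8,,
714.0,13,13.1,13.1.1,13.1.1.1
715.0,13,13.2,13.2.1,
721.0,13,13.2,13.2.2,13.2.2.1
401.1,7,7.1,7.1.1,7.1.1.1
V10.1,2,2.1,,
E850.0,16,16.1,16.1.1,
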