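patient_id,organ,diameter_mm
P1,lung,6.5
P1,lung,7.5
P1,lung,7.0
P1,lung,12.0
P2,liver,15
P2,liver,16
P2,liver,30
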