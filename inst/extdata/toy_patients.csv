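patient_id,sex,primary_location,timing,months_primary_to_mets,followup_from_primary_months,event
P1,female,head,synchronous,0,9,died
P2,male,tail,metachronous,5,17,censored
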