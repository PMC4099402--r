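visit_id,patient_id,visit_date,dx1,dx2,dx3,modality
V000001,P001,2005-03-14,6254,,,CHM
V000002,P002,2005-03-15,625.4,,,CHM;ACUPUNCTURE
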