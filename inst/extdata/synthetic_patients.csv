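patient_id,age,differentiation,histology,lymph_node_count,cea,ca199,lvi,lnr,t_stage,n_stage,stage_group
p1,75,poor,mucinous_adenocarcinoma,8,9.0,20,no,0.40,T4,N2,IIIC
p2,62,moderate,adenocarcinoma,15,3.2,12,no,0.05,T2,N0,I
p3,48,poor,adenocarcinoma,22,6.8,55,yes,0.21,T3,N1,IIIB
p4,55,well,adenocarcinoma,12,1.1,8,no,0.00,T1,N0,I
p5,69,poor,adenocarcinoma,18,4.9,36.5,no,0.12,T3,N0,IIA
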