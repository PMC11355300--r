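algorithm,rank1,rank2,rank3,rank4,ad_position
mlp,aop_deg,hsd_mm,mla_deg,ad_mm,4
rf,mla_deg,hsd_mm,ad_mm,aop_deg,3
svm,hsd_mm,ad_mm,mla_deg,aop_deg,2
xgboost,hsd_mm,ad_mm,mla_deg,NA,2
lr,hsd_mm,mla_deg,aop_deg,ad_mm,4
dt,mla_deg,aop_deg,ad_mm,hsd_mm,3
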