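pair,feature,direction,threshold,predicted
AD-AoP,aop_deg,<,101.5,ICD
AD-AoP,aop_deg,>=,144.5,ICD
AD-AoP,ad_mm,>=,67,ICD
AD-HSD,ad_mm,>=,70.5,ICD
AD-HSD,hsd_mm,>=,19.5,ICD
AD-MLA,ad_mm,>=,65.5,ICD
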