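# reference encapsulation efficiencies (HPLC) and loading concentrations of
# the encapsulated compounds in each formulation
formulation,compound,c_initial_ug_ml,ee_pct,ee_sd
ACT,ACT,62.5,84.83,1.68
ACT+CBD,ACT,31.2,85.23,0.81
ACT+CBD,CBD,15.7,100.26,0.65
ACT+NG,ACT,50.0,85.70,0.82
ACT+NG,NG,5.4,99.19,0.33
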