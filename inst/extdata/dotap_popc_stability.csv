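# reference 21-day characterization of DOTAP:POPC (2:8) liposomes carrying
# acteoside alone or co-loaded with cannabidiol or naringenin; size_nm values
# are as exported by the instrument (the ACT+CBD day-0 size is missing its
# decimal separator; see read_formulation_table)
formulation,timepoint_days,size_nm,size_sd,pdi,pdi_sd,zeta_mv,zeta_sd
DOTAP:POPC,0,128.9,5.0,0.21,0.01,34.3,1.7
ACT,0,126.0,7.7,0.17,0.07,33.3,3.6
ACT+CBD,0,1273,6.0,0.19,0.05,37.3,0.6
ACT+NG,0,129.3,25.1,0.17,0.07,33.9,3.3
DOTAP:POPC,7,141.8,40.3,0.21,0.04,39.7,0.4
ACT,7,133.4,16.3,0.21,0.03,37.3,2.8
ACT+CBD,7,144.6,9.6,0.24,0.02,36.0,2.5
ACT+NG,7,142.2,28.7,0.21,0.07,34.6,3.9
DOTAP:POPC,14,154.3,40.5,0.25,0.03,38.6,2.1
ACT,14,190.6,54.5,0.23,0.03,38.7,1.3
ACT+CBD,14,153.4,29.3,0.25,0.04,37.3,0.5
ACT+NG,14,182.1,59.3,0.23,0.04,37.2,3.8
DOTAP:POPC,21,146.7,39.1,0.23,0.06,39.5,4.1
ACT,21,136.9,6.4,0.21,0.04,39.9,2.1
ACT+CBD,21,142.9,18.5,0.22,0.03,39.5,3.2
ACT+NG,21,147.8,6.6,0.22,0.08,34.1,2.6
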