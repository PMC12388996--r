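# reference IC50 values (uM) of the nanoformulations against two glioma lines
# (U-87 MG, U-138 MG) and non-cancerous MRC-5 fibroblasts at 24 h and 48 h
formulation,cell_line,timepoint_h,ic50_um
DOTAP:POPC,U-87 MG,24,18
DOTAP:POPC,U-87 MG,48,16
DOTAP:POPC,U-138 MG,24,17
DOTAP:POPC,U-138 MG,48,15
DOTAP:POPC,MRC-5,24,20
DOTAP:POPC,MRC-5,48,19
ACT+CBD,U-87 MG,24,11
ACT+CBD,U-87 MG,48,7
ACT+CBD,U-138 MG,24,10
ACT+CBD,U-138 MG,48,6
ACT+CBD,MRC-5,24,12
ACT+CBD,MRC-5,48,9
ACT+NG,U-87 MG,24,9
ACT+NG,U-87 MG,48,6
ACT+NG,U-138 MG,24,8
ACT+NG,U-138 MG,48,5
ACT+NG,MRC-5,24,10
ACT+NG,MRC-5,48,8
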