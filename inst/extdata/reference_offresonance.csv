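# reference off-resonance fit results: relaxation enhancement factor K (with
# fit uncertainty) and rotational correlation time per liposomal system, at
# 30.2 MHz proton frequency and B1 = 5 G
material,K,K_err,tau_c_ns
ACT,1.22,0.17,1.8
ACT+CBD,1.46,0.27,2.8
ACT+NG,1.72,0.21,3.6
DOTAP:POPC,1.61,0.22,3.2
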