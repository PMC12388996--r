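# reference laboratory-frame relaxation parameters of the liposomal systems:
# spin-lattice T1 and the Gaussian/Lorentzian decomposition of the transverse
# decay (amplitude percentages and component T2 values)
material,T1_s,M0G_pct,T2G_ms,M0L_pct,T2L_ms
ACT,2.5,58,184,42,300.0
ACT+CBD,2.6,77,232,23,7.6
ACT+NG,2.7,86,188,14,118.0
DOTAP:POPC,2.6,62,186,38,352.0
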