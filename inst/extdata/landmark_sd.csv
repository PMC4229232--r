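landmark,sd_x_mm,sd_y_mm,sd_z_mm
SACRUM,0.7,0.6,1.8
RASIS,1.6,0.4,2.6
RPSIS,0.8,0.3,2.1
LASIS,1.2,0.6,2.3
LPSIS,0.9,0.4,2.8
RGT,1.0,1.4,1.1
RME,0.4,0.7,1.3
RLE,0.6,1.6,1.3
RHC,0.6,0.8,1.5
RHF,2.2,0.8,0.3
RTT,3.5,1.3,4.2
RLC,0.7,3.5,1.2
RMC,0.5,1.5,0.6
RMM,1.6,0.9,0.5
RLM,0.7,0.5,0.3
RCA,1.1,1.0,0.3
RFM,0.8,1.6,0.1
RSM,0.8,0.7,1.0
RVM,0.7,0.7,0.4
RPAI,0.6,1.4,0.1
RPAII,0.6,0.5,0.0
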