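solvent,nucleus,shift_ppm
CDCl3,1H,7.26
DMSO-d6,1H,2.50
CD3OD,1H,3.31
D2O,1H,4.79
acetone-d6,1H,2.05
CD3CN,1H,1.94
C6D6,1H,7.16
CDCl3,13C,77.16
DMSO-d6,13C,39.52
CD3OD,13C,49.00
acetone-d6,13C,29.84
CD3CN,13C,1.32
C6D6,13C,128.06
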