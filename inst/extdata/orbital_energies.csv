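compound,e_homo_ev,e_lumo_ev,dipole_debye,total_energy_hartree
EGCG,-5.4567,-0.9123,4.1266,-1675.696433
Chrysin,-5.9244,-1.4348,3.6727,-877.990789
Apigenin,-5.7215,-1.2744,2.4038,-953.176777
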