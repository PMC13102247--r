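compound_id,E_HOMO,E_LUMO,dipole
IMPHY003213,-0.2385,-0.1261,7.56482
IMPHY003388,-0.2227,-0.1005,1.82226
IMPHY004834,-0.1974,-0.0076,3.7444
IMPHY012536,-0.1839,-0.1083,6.02785
IMPHY014076,-0.217,-0.0843,3.23369
IMPHY014498,-0.2401,-0.1092,0.50868
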