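compound_id,gap,IP,EA,chi,mu,eta,sigma,omega
IMPHY003213,0.1124,0.2385,0.1261,-0.1823,0.1823,0.0562,17.7931,0.29566
IMPHY003388,0.1222,0.2227,0.1005,-0.1616,0.1616,0.0611,16.3666,0.2137
IMPHY004834,0.1898,0.1974,0.0076,-0.1025,0.1025,0.0949,10.5374,0.05535
IMPHY012536,0.0756,0.1839,0.1083,-0.1461,0.1461,0.0378,26.455,0.28234
IMPHY014076,0.1327,0.217,0.0843,-0.15065,0.15065,0.06635,15.07156,0.171028
IMPHY014498,0.1309,0.2401,0.1092,-0.17465,0.17465,0.06545,15.278838,0.2330223
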