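compound_id,vdw_mean,vdw_sd,elec_mean,elec_sd,polar_solv_mean,polar_solv_sd,sasa_mean,sasa_sd,total_mean,total_sd
IMPHY003213,-18.245,0.025,-21.340,0.348,-16.890,13.767,-3.548,0.312,-60.023,13.775
IMPHY012536,-38.488,2.091,2.078,3.454,-24.725,3.987,-4.597,0.439,-65.732,5.691
IMPHY004834,-66.150,3.326,-113.386,6.462,114.796,7.282,-20.562,0.264,-85.302,10.291
IMPHY003388,-76.022,3.549,-26.748,2.482,48.358,5.332,-8.602,0.722,-63.014,6.907
IMPHY014076,-16.120,0.014,-18.840,0.807,-14.680,0.682,-3.333,0.142,-52.973,1.066
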