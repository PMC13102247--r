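compound_id,rmsd_mean,rmsd_sd,rmsf_mean,rmsf_sd,rg_mean,rg_sd,sasa_mean,sasa_sd
IMPHY003213,3.428,0.501,1.707,1.076,14.395,0.119,80.97,2.76
IMPHY003388,3.394,0.518,1.758,1.232,14.380,0.138,79.91,3.06
IMPHY004834,3.714,0.368,1.601,0.958,14.458,0.098,78.48,2.32
IMPHY012536,3.440,0.400,1.613,1.096,14.361,0.131,78.19,2.97
IMPHY014076,3.641,0.355,1.726,0.971,14.340,0.106,79.34,3.06
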