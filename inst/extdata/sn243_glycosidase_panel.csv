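substrate,KM_droplets_mM,KM_droplets_sd_mM,kcat_droplets_per_s,kcat_droplets_sd_per_s,kcat_over_KM_droplets_per_M_s,KM_plate_mM,KM_plate_sd_mM,kcat_plate_per_s,kcat_plate_sd_per_s,kcat_over_KM_plate_per_M_s,substrate_stock_mM,enzyme_nM
pNP-b-GlcA,0.0150,0.0036,22.2,6.2,1.5e6,0.0137,0.0009,23.1,0.2,1.7e6,0.5,5
pNP-b-Glc,36.8,9.0,0.7,0.1,1.9e1,56.5,4.1,0.7,0.03,1.3e1,400,1000
pNP-b-GalA,1.6,0.3,13.4,2.0,8.2e3,1.0,0.1,16.6,0.7,1.6e4,100,25
pNP-b-Gal,75.8,7.7,0.036,0.003,4.7e-1,38.7,4.6,0.012,0.001,3.1e-1,400,10000
pNP-b-Xyl,21.9,1.6,0.4,0.02,1.8e1,23.0,0.9,0.4,0.01,1.8e1,400,1000
pNP-a-Araf,107.8,35.0,0.027,0.007,2.6e-1,84.5,9.3,0.014,0.001,1.7e-1,400,10000
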