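substrate,detection_point,KM_mM,kcat_per_s,kcat_over_KM_per_M_s
pNP-b-GalA,1,1.2,16.3,1.4e4
pNP-b-GalA,2,1.0,15.0,1.4e4
pNP-b-GalA,3,0.74,12.3,1.7e4
pNP-b-GalA,4,0.75,12.5,1.7e4
pNP-b-Gal,5,79.0,0.043,5.5e-1
pNP-b-Gal,6,79.6,0.052,6.5e-1
pNP-b-Gal,7,70.5,0.043,6.1e-1
pNP-b-Gal,8,80.8,0.044,5.5e-1
pNP-b-Xyl,9,23.5,0.48,2.0e1
pNP-b-Xyl,10,22.1,0.57,2.6e1
pNP-b-Xyl,11,22.0,0.55,2.5e1
pNP-b-Xyl,12,20.2,0.54,2.7e1
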