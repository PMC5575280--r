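morphotype,species,induction,thickness_median_um,layers_median,afm_modulus_mean_mpa,afm_modulus_sd_mpa,structural_modulus_mean_kpa,structural_modulus_sd_kpa,critical_force_mean_mn,critical_force_sd_mn,laminate_model,cylinders
D. pulex uninduced,pulex,uninduced,0.843,9,1.66,1.71,142.38,167.58,1.14,0.87,i,13
D. pulex induced,pulex,induced,1.358,11,2.93,1.92,262.84,209.33,1.84,1.50,ii,16
D. longicephala uninduced,longicephala,uninduced,0.919,6,5.12,12.33,103.96,114.34,2.22,0.94,iii,9
D. longicephala induced,longicephala,induced,1.041,9,15.59,21.55,195.39,182.98,3.07,1.18,i,13
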