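stream,sample_size,collection_year,spawning_year,tfm_year,years_since_tfm,nc,nc_cv,nc_year,drainage_ha,n_sites,sampling_distance_km,nb_ld,nb_ld_lo,nb_ld_hi,nb_sf,nb_sf_lo,nb_sf_hi,ns,chao,chao_pm,kbar,vk
Bad,37,2019,2019,2017,2,4333,32,2018,2270,1,0.2,3,2,3,6,3,15,9,10,2,8.2,37.1
Betsie,80,2019,2018,2017,1,1654,,2018,590,1,0.2,62,48,82,80,55,116,79,97,48,2.0,1.9
Betsy,123,2019,2018,2017,1,1097,11,2018,230,2,4,57,46,73,80,59,108,104,165,46,2.4,4.0
Brule,33,2019,2018,2018,0,36558,13,2018,408,1,0.2,68,37,218,111,68,208,51,161,37,1.3,0.4
Cattaraugus,240,2019,2018,2016,2,1637,70,2018,1129,4,11,33,29,37,40,27,65,70,76,29,6.9,42.4
Pigeon,51,2019,2019,2016,3,,,,1550,3,6,7,6,9,4,2,12,10,11,6,10.2,177.8
East Au Gres,21,2019,2018,2018,0,2124,13,2018,653,2,3,0.2,0.2,0.3,7,3,21,8,8,0.2,5.3,7.2
Ford,122,2019,2018,2017,1,,,,1216,1,0.2,38,29,52,40,26,63,113,182,29,2.2,10.5
Manistique,29,2019,2018,2016,2,10420,4,2018,3631,1,0.2,7,4,10,11,6,27,15,27,4,3.9,8.1
Manistee,185,2019,2018,2016,2,7219,21,2018,546,1,0.2,144,117,184,207,167,262,207,440,117,1.8,1.8
Middle,444,2017,2016,2013,3,4705,,2016,142,7,6,228,202,259,353,302,420,402,545,202,2.2,2.9
Misery,37,2019,2018,2015,4,,,,102,1,0.2,9,7,11,9,5,24,14,14,7,5.3,17.6
Muskegon,53,2019,2018,2017,1,,,,7327,1,0.2,249,172,428,367,237,764,91,279,172,1.2,0.1
Ocqueoc,121,2019,2018,2016,2,4813,5,2018,363,2,3,133,102,182,180,140,239,145,239,27,1.7,1.1
Swan,38,2019,2018,2013,5,,,,5,1,0.2,2,2,2,4,2,12,5,5,2,15.2,56.6
Tahquamenon,92,2019,2018,2015,3,3974,9,2018,2176,1,0.2,50,38,70,68,47,70,82,121,38,2.2,3.2
Two-hearted,43,2019,2018,2016,2,,,,521,1,0.2,25,17,40,30,18,51,42,77,20,2.0,3.6
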