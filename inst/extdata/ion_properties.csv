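ion,kind,charge,mass_g_mol,periodic_group,nutrient_class
K,cation,1,39.098,1,macronutrient
NH4,cation,1,18.039,15,macronutrient
Na,cation,1,22.990,1,sodium
Ca,cation,2,40.078,2,secondary_nutrient
Mg,cation,2,24.305,2,secondary_nutrient
Ag,cation,1,107.868,11,heavy_metal
Ba,cation,2,137.327,2,heavy_metal
Cd,cation,2,112.411,12,heavy_metal
Cu,cation,2,63.546,11,heavy_metal
La,cation,3,138.905,3,heavy_metal
Ni,cation,2,58.693,10,heavy_metal
Gd,cation,3,157.250,3,heavy_metal
Cl,anion,-1,35.453,17,micronutrient
NO3,anion,-1,62.004,15,macronutrient
SO4,anion,-2,96.060,16,secondary_nutrient
H2PO4,anion,-1,96.987,15,macronutrient
CO3,anion,-2,60.009,14,neutral
OH,anion,-1,17.008,16,neutral
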