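name,kind,label,diameter_um,diameter_sd_um,membrane_thickness_nm,membrane_conductivity_S_m,membrane_relative_permittivity,cytoplasm_conductivity_S_m,cytoplasm_relative_permittivity,conductivity_S_m,relative_permittivity
PBS,medium,,,,,,,,,1.6,78
polystyrene,bead,OTHER,10,0,,,,,,0,2.5
WBC,cell,WBC,9,1.5,7,1e-7,6.5,0.65,60,,
MCF-7,cell,TUMOR,18,2.5,7,1e-7,12.5,0.50,60,,
A549,cell,TUMOR,17,2.5,7,1e-7,11.0,0.55,60,,
SW480,cell,TUMOR,17.5,2.5,7,1e-7,13.0,0.45,60,,
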