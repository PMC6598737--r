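{
  "groups": {
    "region": ["occipital_pole", "calcarine_cortex", "cuneus", "lingual_gyrus", "inferior_occipital_gyrus", "middle_occipital_gyrus", "superior_occipital_gyrus", "occipital_fusiform_gyrus", "postcentral_gyrus", "precuneus", "superior_parietal_lobule", "supramarginal_gyrus", "angular_gyrus", "parietal_operculum", "posterior_cingulate_gyrus", "fusiform_gyrus", "inferior_temporal_gyrus", "middle_temporal_gyrus", "superior_temporal_gyrus", "temporal_pole", "planum_polare", "planum_temporale", "transverse_temporal_gyrus", "parahippocampal_gyrus", "precentral_gyrus", "superior_frontal_gyrus", "middle_frontal_gyrus", "opercular_inferior_frontal_gyrus", "orbital_inferior_frontal_gyrus", "triangular_inferior_frontal_gyrus", "medial_frontal_cortex", "supplementary_motor_cortex", "frontal_operculum", "frontal_pole", "gyrus_rectus", "anterior_orbital_gyrus", "medial_orbital_gyrus", "lateral_orbital_gyrus", "posterior_orbital_gyrus", "central_operculum", "anterior_cingulate_gyrus", "hippocampus", "entorhinal_area", "lateral_ventricle", "inferior_lateral_ventricle", "whole_brain"],
    "roi": ["occipital", "occipital", "occipital", "occipital", "occipital", "occipital", "occipital", "occipital", "parietal", "parietal", "parietal", "parietal", "parietal", "parietal", "parietal", "temporal", "temporal", "temporal", "temporal", "temporal", "temporal", "temporal", "temporal", "temporal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "frontal", "hippocampal", "entorhinal", "ventricle", "ventricle", "whole_brain"]
  },
  "pairs": {
    "left": ["left_occipital_pole", "left_calcarine_cortex", "left_cuneus", "left_lingual_gyrus", "left_inferior_occipital_gyrus", "left_middle_occipital_gyrus", "left_superior_occipital_gyrus", "left_occipital_fusiform_gyrus", "left_postcentral_gyrus", "left_precuneus", "left_superior_parietal_lobule", "left_supramarginal_gyrus", "left_angular_gyrus", "left_parietal_operculum", "left_posterior_cingulate_gyrus", "left_fusiform_gyrus", "left_inferior_temporal_gyrus", "left_middle_temporal_gyrus", "left_superior_temporal_gyrus", "left_temporal_pole", "left_planum_polare", "left_planum_temporale", "left_transverse_temporal_gyrus", "left_parahippocampal_gyrus", "left_precentral_gyrus", "left_superior_frontal_gyrus", "left_middle_frontal_gyrus", "left_opercular_inferior_frontal_gyrus", "left_orbital_inferior_frontal_gyrus", "left_triangular_inferior_frontal_gyrus", "left_medial_frontal_cortex", "left_supplementary_motor_cortex", "left_frontal_operculum", "left_frontal_pole", "left_gyrus_rectus", "left_anterior_orbital_gyrus", "left_medial_orbital_gyrus", "left_lateral_orbital_gyrus", "left_posterior_orbital_gyrus", "left_central_operculum", "left_anterior_cingulate_gyrus", "left_hippocampus", "left_entorhinal_area", "left_lateral_ventricle", "left_inferior_lateral_ventricle"],
    "right": ["right_occipital_pole", "right_calcarine_cortex", "right_cuneus", "right_lingual_gyrus", "right_inferior_occipital_gyrus", "right_middle_occipital_gyrus", "right_superior_occipital_gyrus", "right_occipital_fusiform_gyrus", "right_postcentral_gyrus", "right_precuneus", "right_superior_parietal_lobule", "right_supramarginal_gyrus", "right_angular_gyrus", "right_parietal_operculum", "right_posterior_cingulate_gyrus", "right_fusiform_gyrus", "right_inferior_temporal_gyrus", "right_middle_temporal_gyrus", "right_superior_temporal_gyrus", "right_temporal_pole", "right_planum_polare", "right_planum_temporale", "right_transverse_temporal_gyrus", "right_parahippocampal_gyrus", "right_precentral_gyrus", "right_superior_frontal_gyrus", "right_middle_frontal_gyrus", "right_opercular_inferior_frontal_gyrus", "right_orbital_inferior_frontal_gyrus", "right_triangular_inferior_frontal_gyrus", "right_medial_frontal_cortex", "right_supplementary_motor_cortex", "right_frontal_operculum", "right_frontal_pole", "right_gyrus_rectus", "right_anterior_orbital_gyrus", "right_medial_orbital_gyrus", "right_lateral_orbital_gyrus", "right_posterior_orbital_gyrus", "right_central_operculum", "right_anterior_cingulate_gyrus", "right_hippocampus", "right_entorhinal_area", "right_lateral_ventricle", "right_inferior_lateral_ventricle"],
    "region": ["occipital_pole", "calcarine_cortex", "cuneus", "lingual_gyrus", "inferior_occipital_gyrus", "middle_occipital_gyrus", "superior_occipital_gyrus", "occipital_fusiform_gyrus", "postcentral_gyrus", "precuneus", "superior_parietal_lobule", "supramarginal_gyrus", "angular_gyrus", "parietal_operculum", "posterior_cingulate_gyrus", "fusiform_gyrus", "inferior_temporal_gyrus", "middle_temporal_gyrus", "superior_temporal_gyrus", "temporal_pole", "planum_polare", "planum_temporale", "transverse_temporal_gyrus", "parahippocampal_gyrus", "precentral_gyrus", "superior_frontal_gyrus", "middle_frontal_gyrus", "opercular_inferior_frontal_gyrus", "orbital_inferior_frontal_gyrus", "triangular_inferior_frontal_gyrus", "medial_frontal_cortex", "supplementary_motor_cortex", "frontal_operculum", "frontal_pole", "gyrus_rectus", "anterior_orbital_gyrus", "medial_orbital_gyrus", "lateral_orbital_gyrus", "posterior_orbital_gyrus", "central_operculum", "anterior_cingulate_gyrus", "hippocampus", "entorhinal_area", "lateral_ventricle", "inferior_lateral_ventricle"]
  },
  "drop": []
}
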