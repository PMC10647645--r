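{
 "DMN": [
  "lh_medialorbitofrontal",
  "rh_medialorbitofrontal",
  "lh_rostralanteriorcingulate",
  "rh_rostralanteriorcingulate",
  "lh_posteriorcingulate",
  "rh_posteriorcingulate",
  "lh_isthmuscingulate",
  "rh_isthmuscingulate",
  "lh_precuneus",
  "rh_precuneus",
  "lh_inferiorparietal",
  "rh_inferiorparietal",
  "lh_middletemporal",
  "rh_middletemporal",
  "lh_parahippocampal",
  "rh_parahippocampal",
  "lh_entorhinal",
  "rh_entorhinal",
  "lh_temporalpole",
  "rh_temporalpole",
  "lh_frontalpole",
  "rh_frontalpole",
  "lh_superiorfrontal",
  "rh_superiorfrontal"
 ],
 "DAN": [
  "lh_superiorparietal",
  "rh_superiorparietal",
  "lh_supramarginal",
  "rh_supramarginal",
  "lh_caudalmiddlefrontal",
  "rh_caudalmiddlefrontal",
  "lh_precentral",
  "rh_precentral",
  "lh_postcentral",
  "rh_postcentral",
  "lh_paracentral",
  "rh_paracentral",
  "lh_bankssts",
  "rh_bankssts"
 ],
 "SAN": [
  "lh_insula",
  "rh_insula",
  "lh_caudalanteriorcingulate",
  "rh_caudalanteriorcingulate",
  "lh_rostralmiddlefrontal",
  "rh_rostralmiddlefrontal",
  "lh_parsopercularis",
  "rh_parsopercularis",
  "lh_parstriangularis",
  "rh_parstriangularis",
  "lh_parsorbitalis",
  "rh_parsorbitalis",
  "lh_lateralorbitofrontal",
  "rh_lateralorbitofrontal",
  "lh_superiortemporal",
  "rh_superiortemporal",
  "lh_transversetemporal",
  "rh_transversetemporal"
 ],
 "VIS": [
  "lh_pericalcarine",
  "rh_pericalcarine",
  "lh_cuneus",
  "rh_cuneus",
  "lh_lingual",
  "rh_lingual",
  "lh_lateraloccipital",
  "rh_lateraloccipital",
  "lh_fusiform",
  "rh_fusiform",
  "lh_inferiortemporal",
  "rh_inferiortemporal"
 ]
}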