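{
  "VmaxGastric": 0.10028847533601028,
  "KmGastric": 0.81154712950532315,
  "k_kcalscaling": 0.026009077044725923,
  "km_kcal": 7219.025648168511,
  "n_kcal": 2.9350431505014307,
  "k_poolIn": 0.049215056963481905,
  "k_poolOut": 0.00011026963373147828,
  "VmaxADHSto": 383.0316652068957,
  "KmADHSto": 1750.8565753331234,
  "k_EtOHuptake": 0.050859315786513391,
  "k_equalize": 3.3642850961064519,
  "k_equalize_liver": 0.56649349325150178,
  "VmaxADH": 17.490115599723829,
  "VmaxCYP2E1": 0.77158829561312858,
  "KmADH": 12.13180346563429,
  "KmCYP2E1": 45.985404295424779,
  "k_food_clearance": 0.13502427745939469,
  "k_acetate": 1.1650870599405063,
  "k_blood_plasma_ratio": 0.68717298665863957,
  "k_urine_water": 5.9617119565460372,
  "k_basal_vasopressin": 0.38495874093108179,
  "k_vasopressin_BAC": 74740.434017682914,
  "k_clearance_vasopressin": 0.00066266304404711792,
  "k_kidney_permability": 2.5215624280668018e-05,
  "VmaxEtG": 0.6461457040480787,
  "KmEtG": 29854.322456892394,
  "VmaxEtS": 0.011876595138349037,
  "KmEtS": 414.40740948670106,
  "k_EtG_urine": 0.0024879684263205454,
  "k_EtS_urine": 0.014152433882270748,
  "k_PEth": 0.13959486810293995,
  "k_PEth_clearance": 0.001460712263112933,
  "k_PEth_bind": 0.078057399123574775,
  "k_PEth_release": 0.0028510443200615771
}
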