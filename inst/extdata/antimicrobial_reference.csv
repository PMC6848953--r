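name,formula,source,notes
O-glycoside-aglycones apigenin,C15H10O5,CBD,
O-glycoside-luteolin,C15H10O6,CBD,isomer of kaempferol; confirmed by LC-MS/MS
Tetrahydrocannabinolic acid,C22H30O4,CBD,
O-glycoside-kaempferol,C21H20O11,CBD,isomer of luteolin glucoside; confirmed by LC-MS/MS
Umbelliferone,C9H6O3,Chamomile,
Isorhamnetin,C16H12O7,Chamomile,
Luteolin glucoside,C21H20O11,Chamomile,isomer of O-glycoside-kaempferol; confirmed by LC-MS/MS
Quercetin glycoside,C21H20O12,Chamomile,
Coumaric acid,C9H8O3,Chia,
Quinic acid,C7H12O6,Chia,
Syringic acid-glucoside,C15H18O9,Chia,
Caffeoylquinic acid,C16H18O9,Chia,confirmed by LC-MS/MS
Methyl rosmarinic acid-glucoside,C18H16O8,Chia,
Dodecanoic acid,C12H24O2,Cinnamon,possible lipid isomer - fatty acid 12:0
Palmitic acid ethyl ester,C18H36O2,Creosote,
Veratric acid,C9H10O4,Mullein,
Kaempferol,C15H10O6,Senna,isomer of O-glycoside-luteolin; confirmed by LC-MS/MS
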