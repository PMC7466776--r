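drug,multiplex_allowed,half_life_min,t_imax_min,q_max,q_max_unit,concentration,conc_unit,category
amiodarone,yes,60,15,100,mg/min,12,mg/ml,other
amoxicilin,yes,75,17,250,mg/min,20,mg/ml,other
ceftazidime,yes,180,45,500,mg/min,42,mg/ml,other
clindamycin,yes,180,45,30,mg/min,38,mg/ml,other
clonidine,yes,40,20,15,ug/min,10,ug/ml,vasoactive
dexmedetomidine,yes,120,15,6,ug/min,8,ug/ml,analgesic_sedative
dobutamine,no,2,0,,,5,mg/ml,vasoactive
dopamine,no,2,0,,,4,mg/ml,vasoactive
epinephrine/adrenalin,no,2,0,,,0.1,mg/ml,vasoactive
esomeprazole,yes,120,100,4,mg/min,1.6,mg/ml,other
fentanyl,yes,20,10,25,ug/min,0.05,mg/ml,analgesic_sedative
phenylephrine,no,4,1,15,ug/min,0.1,mg/ml,vasoactive
flucloxacillin,yes,120,30,500,mg/min,50,mg/ml,other
furosemide,yes,60,30,20,mg/min,5.0,mg/ml,other
gentamycin,yes,120,15,33,mg/min,1,mg/ml,other
heparin,yes,15,30,1500,IU/min,400,IU/ml,other
hydrocortisone,yes,180,90,50,mg/min,4,mg/ml,other
insulin,undetermined,15,15,0.8,IU/min,1,IU/ml,dedicated_lumen
potassium chloride,yes,60,30,0.3,mmol/min,1,mmol/ml,other
s-ketamine,yes,10,5,5,mg/min,5,mg/ml,analgesic_sedative
methylprednisolone,yes,120,90,30,mg/min,60,mg/ml,other
magnesium sulfate,yes,60,60,200,mg/min,100,mg/ml,other
midazolam,yes,15,25,2,mg/min,2,mg/ml,analgesic_sedative
milrinone,yes,140,30,0.3,mg/min,0.2,mg/ml,vasoactive
morphine,yes,20,15,4,mg/min,1,mg/ml,analgesic_sedative
nicardipine,yes,30,30,0.5,mg/min,1.0,mg/ml,vasoactive
nitroglycerin,no,15,7,0.5,mg/min,0.5,mg/ml,vasoactive
norepinephrine/noradrenalin,no,2,0,,,0.1,mg/ml,vasoactive
paracetamol,yes,120,60,60,mg/min,10,mg/ml,analgesic_sedative
propofol,yes,15,4,200,mg/min,20,mg/ml,analgesic_sedative
sufentanil,yes,30,30,25,ug/min,10,ug/ml,analgesic_sedative
tacrolimus,yes,240,60,7,ug/min,40,ug/ml,other
tobramycin,yes,120,15,8,mg/min,6,mg/ml,other
vancomycin,yes,120,60,10,mg/min,40,mg/ml,other
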