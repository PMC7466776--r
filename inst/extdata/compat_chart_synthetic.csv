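drug,amiodarone,amoxicilin,ceftazidime,clindamycin,clonidine,dexmedetomidine,dobutamine,dopamine,epinephrine/adrenalin,esomeprazole,fentanyl,phenylephrine,flucloxacillin,furosemide,gentamycin,heparin,hydrocortisone,insulin,potassium chloride,s-ketamine,methylprednisolone,magnesium sulfate,midazolam,milrinone,morphine,nicardipine,nitroglycerin,norepinephrine/noradrenalin,paracetamol,propofol,sufentanil,tacrolimus,tobramycin,vancomycin
amiodarone,1,0,1,0,1,1,1,1,1,1,0,0,0,0,1,1,0,0,0,0,1,1,1,0,0,0,1,1,0,1,0,0,1,0
amoxicilin,0,1,0,0,1,1,0,0,1,0,1,0,0,0,0,1,0,0,1,0,1,0,0,0,1,1,1,0,1,1,0,1,0,0
ceftazidime,1,0,1,0,0,0,0,1,0,0,1,1,0,1,0,1,0,0,0,1,1,1,1,1,1,1,1,1,0,0,1,0,0,0
clindamycin,0,0,0,1,0,1,0,1,1,1,0,0,0,1,0,0,0,0,0,1,1,0,1,1,1,1,0,0,0,1,0,0,0,0
clonidine,1,1,0,0,1,0,1,1,1,0,0,1,1,1,1,0,0,0,1,0,0,0,0,1,0,1,1,1,1,1,0,1,0,1
dexmedetomidine,1,1,0,1,0,1,1,0,0,0,1,0,1,1,1,0,0,0,1,1,0,0,1,1,1,0,1,0,1,1,1,1,0,1
dobutamine,1,0,0,0,1,1,1,1,1,0,0,1,1,0,1,0,0,1,0,1,1,1,1,1,1,1,1,1,1,1,0,0,0,0
dopamine,1,0,1,1,1,0,1,1,1,1,1,1,0,0,0,1,0,0,1,0,0,1,0,1,1,1,1,1,1,0,1,0,1,1
epinephrine/adrenalin,1,1,0,1,1,0,1,1,1,1,0,1,1,1,1,0,1,0,1,1,1,1,1,1,0,1,1,1,0,0,1,1,0,0
esomeprazole,1,0,0,1,0,0,0,1,1,1,1,1,0,1,1,1,1,1,1,1,1,0,0,1,1,0,0,1,0,0,0,1,1,0
fentanyl,0,1,1,0,0,1,0,1,0,1,1,0,1,1,0,0,1,1,1,1,0,0,1,1,1,0,1,1,1,1,1,0,1,1
phenylephrine,0,0,1,0,1,0,1,1,1,1,0,1,0,0,0,0,1,0,0,1,1,0,0,1,0,1,1,1,0,1,0,0,1,0
flucloxacillin,0,0,0,0,1,1,1,0,1,0,1,0,1,0,0,0,0,1,0,1,1,0,1,0,0,0,1,1,0,0,1,0,0,0
furosemide,0,0,1,1,1,1,0,0,1,1,1,0,0,1,0,1,1,1,1,0,1,1,0,1,1,0,0,1,0,1,0,0,1,1
gentamycin,1,0,0,0,1,1,1,0,1,1,0,0,0,0,1,1,0,1,1,1,1,0,0,1,0,0,1,0,0,1,0,0,0,0
heparin,1,1,1,0,0,0,0,1,0,1,0,0,0,1,1,1,0,1,1,1,1,0,0,0,0,0,1,0,0,0,1,0,0,1
hydrocortisone,0,0,0,0,0,0,0,0,1,1,1,1,0,1,0,0,1,1,1,1,0,0,1,0,1,1,1,1,0,0,0,1,0,0
insulin,0,0,0,0,0,0,1,0,0,1,1,0,1,1,1,1,1,1,1,1,1,0,1,0,0,1,0,0,1,1,1,1,0,0
potassium chloride,0,1,0,0,1,1,0,1,1,1,1,0,0,1,1,1,1,1,1,0,1,0,1,0,1,0,1,1,0,1,0,0,0,1
s-ketamine,0,0,1,1,0,1,1,0,1,1,1,1,1,0,1,1,1,1,0,1,1,1,1,1,1,0,0,0,1,1,1,0,1,1
methylprednisolone,1,1,1,1,0,0,1,0,1,1,0,1,1,1,1,1,0,1,1,1,1,0,1,0,0,0,1,0,1,0,1,0,0,0
magnesium sulfate,1,0,1,0,0,0,1,1,1,0,0,0,0,1,0,0,0,0,0,1,0,1,0,0,1,0,1,0,1,1,0,1,0,0
midazolam,1,0,1,1,0,1,1,0,1,0,1,0,1,0,0,0,1,1,1,1,1,0,1,0,1,0,1,1,1,1,1,0,0,1
milrinone,0,0,1,1,1,1,1,1,1,1,1,1,0,1,1,0,0,0,0,1,0,0,0,1,1,1,1,1,1,1,0,1,0,1
morphine,0,1,1,1,0,1,1,1,0,1,1,0,0,1,0,0,1,0,1,1,0,1,1,1,1,0,0,0,1,1,1,1,1,1
nicardipine,0,1,1,1,1,0,1,1,1,0,0,1,0,0,0,0,1,1,0,0,0,0,0,1,0,1,1,1,0,1,0,1,0,1
nitroglycerin,1,1,1,0,1,1,1,1,1,0,1,1,1,0,1,1,1,0,1,0,1,1,1,1,0,1,1,1,1,0,0,0,1,1
norepinephrine/noradrenalin,1,0,1,0,1,0,1,1,1,1,1,1,1,1,0,0,1,0,1,0,0,0,1,1,0,1,1,1,1,1,1,1,1,0
paracetamol,0,1,0,0,1,1,1,1,0,0,1,0,0,0,0,0,0,1,0,1,1,1,1,1,1,0,1,1,1,1,1,1,0,0
propofol,1,1,0,1,1,1,1,0,0,0,1,1,0,1,1,0,0,1,1,1,0,1,1,1,1,1,0,1,1,1,1,0,1,0
sufentanil,0,0,1,0,0,1,0,1,1,0,1,0,1,0,0,1,0,1,0,1,1,0,1,0,1,0,0,1,1,1,1,0,1,1
tacrolimus,0,1,0,0,1,1,0,0,1,1,0,0,0,0,0,0,1,1,0,0,0,1,0,1,1,1,0,1,1,0,0,1,1,0
tobramycin,1,0,0,0,0,0,0,1,0,1,1,1,0,1,0,0,0,0,0,1,0,0,0,0,1,0,1,1,0,1,1,1,1,0
vancomycin,0,0,0,0,1,1,0,1,0,0,1,0,0,1,0,1,0,0,1,1,0,0,1,1,1,1,1,0,0,0,1,0,0,1
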