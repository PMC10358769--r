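surface_form,atc_code
metformin,A10BA02
glucophage,A10BA02
gliclazide,A10BB09
glibenclamide,A10BB01
glimepiride,A10BB12
sitagliptin,A10BH01
janumet,A10BD07
dapagliflozin,A10BK01
empagliflozin,A10BX09
acarbose,A10BF01
insulin glargine,A10AE04
insulin degludec,A10AE06
insulin aspart,A10AB05
omeprazole,A02BC01
pantoprazole,A02BC02
esomeprazole,A02BC05
warfarin,B01AA03
clopidogrel,B01AC04
acetylsalicylic acid,B01AC06
aspirin,B01AC06
furosemide,C03CA01
hydrochlorothiazide,C03AA03
indapamide,C03BA11
spironolactone,C03DA01
bisoprolol,C07AB07
metoprolol,C07AB02
carvedilol,C07AG02
nebivolol,C07AB12
amlodipine,C08CA01
lercanidipine,C08CA13
verapamil,C08DA01
ramipril,C09AA05
perindopril,C09AA04
enalapril,C09AA02
losartan,C09CA01
valsartan,C09CA03
telmisartan,C09CA07
simvastatin,C10AA01
atorvastatin,C10AA05
rosuvastatin,C10AA07
fenofibrate,C10AB05
ezetimibe,C10AX09
paracetamol,N02BE01
tramadol,N02AX02
metamizole,N02BB02
diazepam,N05BA01
alprazolam,N05BA12
zolpidem,N05CF02
quetiapine,N05AH04
ibuprofen,M01AE01
diclofenac,M01AB05
naproxen,M01AE02
salbutamol,R03AC02
budesonide,R03BA02
tamsulosin,G04CA02
solifenacin,G04BD08
levothyroxine,H03AA01
amoxicillin,J01CA04
ciprofloxacin,J01MA02
timolol,S01ED01
latanoprost,S01EE01
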