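product_id,name,strength,regimen,condition
esomeprazole,Esomeprazole,20 mg,pack_cycle_28d,dyspepsia
sitagliptin,Sitagliptin,100 mg,standard_30d,diabetes
etoricoxib,Etoricoxib,90 mg,pack_cycle_28d,osteoarthritis
candesartan,Candesartan,16 mg,standard_30d,blood_pressure
rosuvastatin,Rosuvastatin,5 mg,standard_30d,hypercholesterolemia
escitalopram,Escitalopram,10 mg,pack_cycle_28d,depression
zoledronic_acid,Zoledronic acid,5 mg/100 ml,yearly,osteoporosis
salmeterol_fluticasone,Salmeterol/fluticasone,25/50 ug,standard_30d,asthma
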