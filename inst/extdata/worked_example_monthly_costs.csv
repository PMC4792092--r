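country,product_id,monthly_cost
IT,esomeprazole,7.08
IT,sitagliptin,59.22
IT,etoricoxib,17.84
IT,candesartan,11.95
IT,rosuvastatin,22.49
IT,escitalopram,24.97
IT,zoledronic_acid,557.36
IT,salmeterol_fluticasone,41.22
GR,esomeprazole,10.81
GR,sitagliptin,50.22
GR,etoricoxib,14.02
GR,candesartan,12.36
GR,rosuvastatin,11.27
GR,escitalopram,13.23
GR,zoledronic_acid,451.27
GR,salmeterol_fluticasone,34.39
PT,esomeprazole,8.81
PT,sitagliptin,50.53
PT,etoricoxib,16.32
PT,candesartan,22.62
PT,rosuvastatin,17.01
PT,escitalopram,11.52
PT,zoledronic_acid,344.21
PT,salmeterol_fluticasone,36.15
CY,esomeprazole,8.63
CY,sitagliptin,58.37
CY,etoricoxib,23.1
CY,candesartan,28.8
CY,rosuvastatin,28.74
CY,escitalopram,15.39
CY,zoledronic_acid,590.98
CY,salmeterol_fluticasone,41.33
ES,esomeprazole,6.3
ES,sitagliptin,55.72
ES,etoricoxib,20.32
ES,candesartan,25.76
ES,rosuvastatin,18.9
ES,escitalopram,16.66
ES,zoledronic_acid,422.65
ES,salmeterol_fluticasone,39.6
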