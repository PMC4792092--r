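country,gdp_ppp_pc,min_wage
IT,1,992.4
GR,1,878
PT,1,565
CY,1,870
ES,1,748
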