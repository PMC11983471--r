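generic,risk_on_label
atazanavir,yes
topiramate,yes
tenofovir,yes
deferasirox,yes
lopinavir,yes
ritonavir,yes
sodium oxybate,no
adalimumab,no
infliximab,no
interferon beta-1a,no
teriparatide,no
lansoprazole,no
teduglutide,no
xywav,no
metformin,no
lisinopril,no
atorvastatin,no
vedolizumab,no
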