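verbatim,generic,atc
adalimumab,adalimumab,L04AB04
humira,adalimumab,L04AB04
infliximab,infliximab,L04AB02
remicade,infliximab,L04AB02
interferon beta-1a,interferon beta-1a,L03AB07
avonex,interferon beta-1a,L03AB07
rebif,interferon beta-1a,L03AB07
sodium oxybate,sodium oxybate,N07XX04
xyrem,sodium oxybate,N07XX04
xywav,xywav,N07XX11
teriparatide,teriparatide,H05AA02
forteo,teriparatide,H05AA02
atazanavir,atazanavir,J05AE08
reyataz,atazanavir,J05AE08
topiramate,topiramate,N03AX11
topamax,topiramate,N03AX11
lansoprazole,lansoprazole,A02BC03
prevacid,lansoprazole,A02BC03
teduglutide,teduglutide,A16AX08
gattex,teduglutide,A16AX08
tenofovir,tenofovir,J05AF07
viread,tenofovir,J05AF07
vedolizumab,vedolizumab,L04AA33
entyvio,vedolizumab,L04AA33
deferasirox,deferasirox,V03AC03
exjade,deferasirox,V03AC03
metformin,metformin,A10BA02
glucophage,metformin,A10BA02
lisinopril,lisinopril,C09AA03
atorvastatin,atorvastatin,C10AA05
lipitor,atorvastatin,C10AA05
kaletra,lopinavir + ritonavir,J05AR10
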