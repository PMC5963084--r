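drug,gene,role,evidence
paclitaxel,ABCC1,export,MRP1 efflux of taxanes
paclitaxel,ABCC2,export,MRP2 efflux
paclitaxel,ABCC5,export,MRP5 efflux
docetaxel,ABCC1,export,MRP1 efflux of taxanes
docetaxel,ABCC2,export,MRP2 efflux
docetaxel,ABCC5,export,MRP5 efflux
paclitaxel,CYP2C8,metabolize,primary oxidative metabolism
paclitaxel,CYP3A4,metabolize,oxidative metabolism
paclitaxel,CYP19A1,metabolize,taxane aromatase metabolism
paclitaxel,NR1I2,metabolize,PXR induction of taxane-metabolizing enzymes
paclitaxel,AKR1C3,metabolize,aldo-keto reductase; case annotation
paclitaxel,NQO1,metabolize,quinone oxidoreductase; case annotation
docetaxel,CYP3A4,metabolize,oxidative metabolism
docetaxel,CYP19A1,metabolize,taxane aromatase metabolism
paclitaxel,TUBB1,target,tubulin binding
paclitaxel,MAP2,target,microtubule-associated stabilizer
paclitaxel,MAP4,target,microtubule-associated stabilizer
paclitaxel,MAPT,target,microtubule-associated stabilizer
paclitaxel,TOP2B,target,case annotation
docetaxel,TUBB1,target,tubulin binding
docetaxel,MAP2,target,microtubule-associated stabilizer
docetaxel,MAP4,target,microtubule-associated stabilizer
docetaxel,MAPT,target,microtubule-associated stabilizer
doxorubicin,ABCC1,export,MRP1 efflux of anthracyclines
doxorubicin,ABCC2,export,MRP2 efflux
doxorubicin,ABCC10,export,MRP7 efflux
doxorubicin,ABCG2,export,BCRP efflux
doxorubicin,RALBP1,export,non-ABC efflux
doxorubicin,AKR1A1,metabolize,carbonyl reduction to doxorubicinol
doxorubicin,AKR1C3,metabolize,carbonyl reduction
doxorubicin,NQO1,metabolize,quinone oxidoreductase
doxorubicin,NR1I2,metabolize,PXR induction; case annotation
doxorubicin,TOP2B,target,topoisomerase II poison
doxorubicin,MAP2,target,case annotation
gemcitabine,ABCC1,export,MRP1 efflux
gemcitabine,ABCC10,export,MRP7 efflux
gemcitabine,NT5C,metabolize,nucleotidase dephosphorylation
gemcitabine,DCTD,metabolize,deaminase inactivation
gemcitabine,UPB1,metabolize,pyrimidine degradation
gemcitabine,DPYS,metabolize,pyrimidine degradation
gemcitabine,CMPK1,activate,phosphorylation to active nucleotide
fluorouracil,ABCC1,export,MRP1 efflux
fluorouracil,ABCC5,export,MRP5 efflux of fluoropyrimidines
fluorouracil,DPYD,metabolize,dihydropyrimidine dehydrogenase degradation
fluorouracil,UPB1,metabolize,pyrimidine degradation
fluorouracil,DPYS,metabolize,pyrimidine degradation
fluorouracil,NT5C,metabolize,nucleotidase dephosphorylation
methotrexate,ABCC5,export,MRP5 efflux of antifolates
methotrexate,FOLR1,import,folate receptor uptake
carboplatin,SLC31A1,import,copper transporter CTR1 uptake
carboplatin,RALBP1,export,non-ABC efflux
carboplatin,HMGB1,target,binds platinum-DNA adducts
cisplatin,SLC31A1,import,copper transporter CTR1 uptake
cisplatin,HMGB1,target,binds platinum-DNA adducts
tamoxifen,ESR2,target,estrogen receptor beta
tamoxifen,UGT1A10,metabolize,glucuronidation
tamoxifen,UGT2B15,metabolize,glucuronidation
tamoxifen,CYP2D6,metabolize,oxidative metabolism
tamoxifen,CYP2C8,metabolize,oxidative metabolism; case annotation
tamoxifen,NR1I2,metabolize,PXR induction; case annotation
lapatinib,EGFR,target,kinase inhibition
cetuximab,EGFR,target,receptor blockade
erlotinib,ERBB2,target,kinase inhibition
trastuzumab,ERBB2,target,receptor blockade
topotecan,ABCC2,export,MRP2 efflux
capecitabine,ABCC5,export,MRP5 efflux of fluoropyrimidines
anastrozole,CYP19A1,target,aromatase inhibition
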