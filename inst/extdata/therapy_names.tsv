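macdonald	fluorouracil|leucovorin|radiotherapy
taxol	paclitaxel
taxotere	docetaxel
adriamycin	doxorubicin
paraplatin	carboplatin
platinol	cisplatin
5-fu	fluorouracil
5fu	fluorouracil
xeloda	capecitabine
gemzar	gemcitabine
carbotaxol	carboplatin|paclitaxel
doc/paclitaxel	docetaxel|paclitaxel
carbo/cisplatin	carboplatin|cisplatin
nolvadex	tamoxifen
mtx	methotrexate
herceptin	trastuzumab
erbitux	cetuximab
tarceva	erlotinib
hycamtin	topotecan
arimidex	anastrozole
xrt	radiotherapy
radiation	radiotherapy
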