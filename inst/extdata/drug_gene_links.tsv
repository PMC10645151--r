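# Default drug-gene interaction map: a documented subset of the FDA/CPIC
# actionable drug-gene pairs covering the nine panel genes. User-supplied maps
# with the same schema are accepted by load_panel().
drug	gene	source
clopidogrel	CYP2C19	FDA
codeine	CYP2D6	FDA
simvastatin	SLCO1B1	CPIC
warfarin	VKORC1	FDA
warfarin	CYP2C9	FDA
fluorouracil	DPYD	FDA
capecitabine	DPYD	FDA
azathioprine	TPMT	FDA
mercaptopurine	TPMT	FDA
thioguanine	TPMT	FDA
ivacaftor	CFTR	FDA
ethinyl estradiol	F5	FDA
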