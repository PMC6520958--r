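sequence	activity	citation
AA	ACE-I inhibitor	Cushman et al. 1973
AG	ACE-I inhibitor	Cheung et al. 1980
AS	DPP IV inhibitor	Lan et al. 2015
DG	ACE-I inhibitor	Meisel et al. 2006
GA	ACE-I inhibitor	Cheung et al. 1980
GD	ACE-I inhibitor	Cheung et al. 1980
GGV	HMG-CoA reductase inhibitor	Soares et al. 2015
GK	ACE-I inhibitor	Cheung et al. 1980
GM	ACE-I inhibitor	Cheung et al. 1980
IG	ACE-I inhibitor	Cheung et al. 1980
IH	DPP IV inhibitor	Lan et al. 2015
NH	DPP IV inhibitor	Lan et al. 2015
PK	DPP IV inhibitor	Lan et al. 2015
TM	DPP IV inhibitor	Lan et al. 2015
VK	DPP IV inhibitor	Lan et al. 2015
VK	ACE-I inhibitor	Wang and De Mejia 2005
VR	DPP IV inhibitor	Nongonierma and FitzGerald 2013
VR	ACE-I inhibitor	Gomez-Ruiz et al. 2004
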