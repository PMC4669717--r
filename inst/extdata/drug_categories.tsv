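drug	category
tanespimycin	anti-inflammation
15-delta prostaglandin j2	anti-inflammation
luteolin	anti-inflammation
parthenolide	anti-inflammation
thiostrepton	antibiotics
antimycin a	antibiotics
sulconazole	antibiotics
cycloserine	antibiotics
chlorpromazine	antipsychotics
trifluoperazine	antipsychotics
thioridazine	antipsychotics
prochlorperazine	antipsychotics
fluphenazine	antipsychotics
perphenazine	antipsychotics
piperlongumine	cardiovascular
propafenone	cardiovascular
phenoxybenzamine	cardiovascular
amiodarone	cardiovascular
daunorubicin	chemotherapeutic
camptothecin	chemotherapeutic
thioguanosine	chemotherapeutic
8-azaguanine	chemotherapeutic
gw-8510	chemotherapeutic
ellipticine	chemotherapeutic
cloperastine	others
nitrarine dihydrochloride	others
emetine	others
tyloxapol	others
norcyclobenzaprine	others
trichostatin a	others
pyrvinium	others
bepridil	others
verteporfin	others
vorinostat	others
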