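ligand_id,category
HOH,solvent
DOD,solvent
DMS,solvent
GOL,additive
EDO,additive
PEG,additive
PG4,additive
MPD,additive
TRS,buffer
EPE,buffer
MES,buffer
BME,additive
ACT,salt
FMT,salt
NO3,salt
SO4,salt
PO4,salt
CIT,buffer
TAR,additive
MG,metal
ZN,metal
NA,metal
K,metal
CA,metal
MN,metal
FE,metal
FE2,metal
CU,metal
NI,metal
CO,metal
CD,metal
HG,metal
CL,salt
BR,salt
IOD,salt
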