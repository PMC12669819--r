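treatment,day,species,conc_ug_per_gdw,d13c_permil
DIC w/ CH4,0,crocetane,1.3,-100
DIC w/ CH4,0,archaeol,4.0,-91
DIC w/ CH4,0,MAGE sn2-phy,1.2,-99
DIC w/ CH4,0,FA C16:1w5c,20.7,-61
DIC w/ CH4,0,FA cyC17:0w5.6,1.1,-59
DIC w/ CH4,0,FA C14:0,9.9,-33
DIC w/ CH4,0,FA C16:0,23.4,-33
DIC w/ CH4,0,FA iC15:0,7.3,-38
DIC w/ CH4,0,FA aiC15:0,5.3,-38
DIC w/ CH4,30,crocetane,1.3,-100
DIC w/ CH4,30,archaeol,4.0,-91
DIC w/ CH4,30,MAGE sn2-phy,1.2,-99
DIC w/ CH4,30,FA C16:1w5c,20.7,-61
DIC w/ CH4,30,FA cyC17:0w5.6,1.1,-59
DIC w/ CH4,30,FA C14:0,9.9,-33
DIC w/ CH4,30,FA C16:0,23.4,-33
DIC w/ CH4,30,FA iC15:0,7.3,-38
DIC w/ CH4,30,FA aiC15:0,5.3,-38
DI13C w/ CH4,0,crocetane,1.3,-100
DI13C w/ CH4,0,archaeol,4.0,-91
DI13C w/ CH4,0,MAGE sn2-phy,1.2,-99
DI13C w/ CH4,0,FA C16:1w5c,20.7,-61
DI13C w/ CH4,0,FA cyC17:0w5.6,1.1,-59
DI13C w/ CH4,0,FA C14:0,9.9,-33
DI13C w/ CH4,0,FA C16:0,23.4,-33
DI13C w/ CH4,0,FA iC15:0,7.3,-38
DI13C w/ CH4,0,FA aiC15:0,5.3,-38
DI13C w/ CH4,30,crocetane,1.3,26
DI13C w/ CH4,30,MAGE sn2-phy,1.2,-20.6
DI13C w/ CH4,30,FA C16:1w5c,20.7,332
DI13C w/ CH4,30,FA cyC17:0w5.6,1.1,199
DI13C w/ CH4,30,FA C14:0,9.9,139
DI13C w/ CH4,30,FA C16:0,23.4,96
DI13C w/ CH4,30,FA iC15:0,7.3,-9.2
DI13C w/ CH4,30,FA aiC15:0,5.3,-0.2
DIC w/ 13CH4,0,crocetane,1.3,-100
DIC w/ 13CH4,0,archaeol,4.0,-91
DIC w/ 13CH4,0,FA C16:1w5c,20.7,-61
DIC w/ 13CH4,0,FA cyC17:0w5.6,1.1,-59
DIC w/ 13CH4,30,crocetane,1.3,-63.1
DIC w/ 13CH4,30,archaeol,4.0,-63.3
DIC w/ 13CH4,30,FA C16:1w5c,20.7,-5.4
DIC w/ 13CH4,30,FA cyC17:0w5.6,1.1,-26.2
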