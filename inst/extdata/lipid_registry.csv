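species,compound_class,formula,group,n_oh_groups
crocetane,hydrocarbon,C20H42,ANME,0
archaeol,alcohol,C43H88O3,ANME,1
sn2-OH-archaeol,alcohol,C43H88O4,ANME,2
MAGE sn2-phy,ether_lipid,C23H48O3,ANME,2
MAGE C16:1w5c,ether_lipid,C19H38O3,SRB,2
DAGE C32:2,ether_lipid,C35H68O3,SRB,1
FA C16:1w5c,fatty_acid,C16H30O2,SRB,0
FA C16:1w7c,fatty_acid,C16H30O2,SRB,0
FA cyC17:0w5.6,fatty_acid,C17H32O2,SRB,0
FA C14:0,fatty_acid,C14H28O2,SRB,0
FA C16:0,fatty_acid,C16H32O2,SRB,0
FA iC15:0,fatty_acid,C15H30O2,background,0
FA aiC15:0,fatty_acid,C15H30O2,background,0
FA C18:1w7c,fatty_acid,C18H34O2,background,0
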