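treatment,sample_type,day,d13c_ch4,d13c_dic,dic_mM,so4_mM,h2s_mM
DIC w/ CH4,sample,0,-43,-11,32,25,0.2
DIC w/ 13CH4,sample,10,9000,205,36,24,1.4
DIC w/ 13CH4,sample,20,15000,918,39,22,3.3
DIC w/ 13CH4,sample,30,11000,1129,41,21,5.9
DI13C w/ CH4,sample,10,-39,5051,34,24,0.9
DI13C w/ CH4,sample,20,-0.6,4905,40,22,3.8
DI13C w/ CH4,sample,30,21,4829,40,20,5.4
DI13C w/o CH4,sample,10,NA,5380,34,24,0.8
DI13C w/o CH4,sample,20,NA,5676,36,25,1.0
DI13C w/o CH4,sample,30,NA,4986,35,25,0.8
DIC w/ 13CH4,control,30,12000,28,4,22,0.0
DI13C w/o CH4,control,30,-43,4841,4,22,0.0
DIC w/ CH4,sample,30,-42,-16,41,21,4.5
DIC w/ 13CH4,blank,30,8000,27,34,26,0.1
DI13C w/o CH4,blank,30,-43,6484,3,26,0.1
DIC w/ CH4,blank,30,-43,-11,34,26,0.1
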