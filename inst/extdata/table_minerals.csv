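hybrid,concentration,part,fe,k,p
ZP434,control,radicle,1.1,1185.5,282.7
ZP434,control,plumule,13.3,979.7,770.0
ZP434,control,ros,11.2,714.7,1090.7
ZP434,5.2e-09,radicle,17.8,1761.3,225.9
ZP434,5.2e-09,plumule,13.3,1412.8,350.1
ZP434,5.2e-09,ros,0.0,482.2,412.0
ZP434,5.2e-12,radicle,8.9,1435.6,131.6
ZP434,5.2e-12,plumule,6.0,1334.4,212.8
ZP434,5.2e-12,ros,3.8,450.7,381.0
ZP434,5.2e-15,radicle,20.8,1428.8,104.3
ZP434,5.2e-15,plumule,6.2,1214.8,213.1
ZP434,5.2e-15,ros,11.0,326.7,316.4
ZP704,control,radicle,3.1,1588.2,1431.6
ZP704,control,plumule,33.2,1746.8,631.5
ZP704,control,ros,30.7,598.2,946.7
ZP704,5.2e-09,radicle,11.2,3199.2,3065.0
ZP704,5.2e-09,plumule,10.7,1756.4,2362.1
ZP704,5.2e-09,ros,25.2,1137.3,5424.7
ZP704,5.2e-12,radicle,60.5,1995.5,1772.2
ZP704,5.2e-12,plumule,23.1,1272.7,1982.9
ZP704,5.2e-12,ros,121.9,1004.5,4564.7
ZP704,5.2e-15,radicle,27.5,1974.9,1968.7
ZP704,5.2e-15,plumule,0.0,1358.1,2015.6
ZP704,5.2e-15,ros,57.7,448.0,3195.0
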