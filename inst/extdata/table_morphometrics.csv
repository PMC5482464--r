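hybrid,concentration,dimension,value_mm,sd_mm
ZP434,control,Seed length,9.1,0.21
ZP434,control,Seed width,6.1,0.08
ZP434,control,Seed thickness,3.8,0.10
ZP434,control,Plumule length,41.2,1.11
ZP434,control,Plumule width,3.2,0.12
ZP434,control,Plumule thickness,1.1,0.06
ZP434,control,Radicle length,186.0,5.13
ZP434,control,Radicle width,1.1,0.06
ZP434,control,Radicle thickness,1.1,0.06
ZP704,control,Seed length,9.9,0.08
ZP704,control,Seed width,6.3,0.06
ZP704,control,Seed thickness,4.0,0.10
ZP704,control,Plumule length,45.1,1.16
ZP704,control,Plumule width,3.4,0.08
ZP704,control,Plumule thickness,1.1,0.06
ZP704,control,Radicle length,191.0,5.77
ZP704,control,Radicle width,1.1,0.06
ZP704,control,Radicle thickness,1.1,0.06
ZP434,5.20e-09,Seed length,9.1,0.08
ZP434,5.20e-09,Seed width,6.1,0.10
ZP434,5.20e-09,Seed thickness,3.8,0.13
ZP434,5.20e-09,Plumule length,38.2,0.40
ZP434,5.20e-09,Plumule width,3.3,0.12
ZP434,5.20e-09,Plumule thickness,1.2,0.06
ZP434,5.20e-09,Radicle length,195.0,2.75
ZP434,5.20e-09,Radicle width,1.1,0.06
ZP434,5.20e-09,Radicle thickness,1.1,0.06
ZP704,5.20e-09,Seed length,9.9,0.09
ZP704,5.20e-09,Seed width,6.3,0.06
ZP704,5.20e-09,Seed thickness,4.0,0.10
ZP704,5.20e-09,Plumule length,42.2,0.67
ZP704,5.20e-09,Plumule width,3.2,0.08
ZP704,5.20e-09,Plumule thickness,1.3,0.06
ZP704,5.20e-09,Radicle length,186.0,4.04
ZP704,5.20e-09,Radicle width,1.1,0.06
ZP704,5.20e-09,Radicle thickness,1.1,0.06
ZP434,5.20e-12,Seed length,9.1,0.08
ZP434,5.20e-12,Seed width,6.1,0.13
ZP434,5.20e-12,Seed thickness,3.8,0.10
ZP434,5.20e-12,Plumule length,38.2,0.70
ZP434,5.20e-12,Plumule width,3.3,0.06
ZP434,5.20e-12,Plumule thickness,1.2,0.04
ZP434,5.20e-12,Radicle length,195.0,3.04
ZP434,5.20e-12,Radicle width,1.1,0.06
ZP434,5.20e-12,Radicle thickness,1.1,0.06
ZP704,5.20e-12,Seed length,9.9,0.13
ZP704,5.20e-12,Seed width,6.3,0.14
ZP704,5.20e-12,Seed thickness,4.0,0.06
ZP704,5.20e-12,Plumule length,41.3,0.49
ZP704,5.20e-12,Plumule width,3.3,0.10
ZP704,5.20e-12,Plumule thickness,1.4,0.06
ZP704,5.20e-12,Radicle length,180.0,3.79
ZP704,5.20e-12,Radicle width,1.1,0.06
ZP704,5.20e-12,Radicle thickness,1.1,0.06
ZP434,5.20e-15,Seed length,9.1,0.10
ZP434,5.20e-15,Seed width,6.1,0.13
ZP434,5.20e-15,Seed thickness,3.8,0.10
ZP434,5.20e-15,Plumule length,55.1,1.62
ZP434,5.20e-15,Plumule width,3.2,0.13
ZP434,5.20e-15,Plumule thickness,1.2,0.03
ZP434,5.20e-15,Radicle length,204.0,4.62
ZP434,5.20e-15,Radicle width,1.1,0.06
ZP434,5.20e-15,Radicle thickness,1.1,0.06
ZP704,5.20e-15,Seed length,9.9,0.10
ZP704,5.20e-15,Seed width,6.3,0.08
ZP704,5.20e-15,Seed thickness,4.0,0.13
ZP704,5.20e-15,Plumule length,42.2,0.95
ZP704,5.20e-15,Plumule width,3.2,0.01
ZP704,5.20e-15,Plumule thickness,1.1,0.10
ZP704,5.20e-15,Radicle length,178.0,3.79
ZP704,5.20e-15,Radicle width,1.1,0.08
ZP704,5.20e-15,Radicle thickness,1.1,0.08
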