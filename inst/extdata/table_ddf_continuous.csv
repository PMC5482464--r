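hybrid,part,family,f0,f0_se,psi,psi_se,mu,mu_se,sigma,sigma_se,rss,chi2
ZP434,radicle,extreme,0.04736,0.00229,0.34469,0.08389,15.74,0.02,0.15,0.02,1.02653e-4,2.56632e-5
ZP434,plumule,extreme,0.02246,0.00163,0.15475,0.02233,15.60,0.02,0.15,0.02,1.81225e-3,4.52332e-4
ZP434,ros,extreme,0.03282,0.00631,0.50056,0.13902,7.10,0.35,0.29,0.05,4.42845e-5,4.14905e-6
ZP704,radicle,lorentz,0.01402,0.00005,0.53760,0.06520,22.11,0.01,1.39,0.04,1.35879e-6,6.79395e-7
ZP704,plumule,lorentz,0.00419,0.00023,0.19311,0.03212,14.70,0.21,0.05,0.01,9.75379e-6,9.01356e-7
ZP704,ros,lorentz,0.02391,0.00051,0.26929,0.09569,14.73,NA,0.56,0.01,1.27484e-6,6.37419e-7
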