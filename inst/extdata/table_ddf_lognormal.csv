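concentration_m,psi,psi_se,a_sharp,a_sharp_se,mu,mu_se,sigma,sigma_se,rss,chi2
5.20e-09,0.51009,0.09125,0.52622,0.05583,19.7,0.1,0.052,0.006,7.12918e-4,3.56459e-5
5.20e-12,0.28021,0.08412,0.35473,0.20372,18.1,0.4,0.016,0.005,1.94671e-4,6.48911e-5
5.20e-15,0.20970,0.06598,0.13667,0.00754,15.5,0.1,0.009,NA,2.58178e-5,2.07110e-6
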