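trait,regime,analysis,environment,sigma2_a,sigma2_d,sigma2_e,rho_a,rho_d,h2,d2,H2
GY,WS,joint,NA,0.60,0.30,0.81,0.35,0.83,0.35,0.17,0.53
GY,WW,joint,NA,1.00,0.45,1.98,0.24,0.85,0.29,0.13,0.42
GY,WS,within,J10,0.64,0.39,0.66,NA,NA,0.38,0.23,0.61
GY,WS,within,T10,0.88,0.11,1.61,NA,NA,0.34,0.04,0.38
GY,WS,within,J11,0.35,0.34,0.33,NA,NA,0.34,0.33,0.68
GY,WS,within,T11,0.50,0.71,0.44,NA,NA,0.30,0.43,0.73
GY,WW,within,J10,1.47,0.56,0.53,NA,NA,0.57,0.22,0.79
GY,WW,within,T10,1.15,0.61,1.02,NA,NA,0.41,0.22,0.63
GY,WW,within,J11,1.59,1.42,1.83,NA,NA,0.33,0.29,0.62
GY,WW,within,T11,0.96,0.45,3.30,NA,NA,0.20,0.10,0.30
FFT,WS,joint,NA,4.66,1.16,4.54,0.64,0.43,0.45,0.11,0.56
FFT,WW,joint,NA,3.13,0.82,1.64,0.82,0.37,0.56,0.15,0.71
FFT,WS,within,J10,6.86,0.75,0.97,NA,NA,0.80,0.09,0.89
FFT,WS,within,T10,1.54,0.12,14.73,NA,NA,0.09,0.01,0.10
FFT,WS,within,J11,6.85,1.88,1.73,NA,NA,0.65,0.18,0.83
FFT,WS,within,T11,2.04,1.20,1.40,NA,NA,0.44,0.26,0.70
FFT,WW,within,J10,4.24,0.83,0.69,NA,NA,0.74,0.14,0.88
FFT,WW,within,T10,2.93,1.15,1.88,NA,NA,0.49,0.19,0.68
FFT,WW,within,J11,3.42,0.45,2.70,NA,NA,0.52,0.07,0.59
FFT,WW,within,T11,2.38,1.03,1.04,NA,NA,0.54,0.23,0.77
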