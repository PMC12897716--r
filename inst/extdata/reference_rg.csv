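temperature_K,rg_langevin_A,sem_langevin_A,rg_dpd_A,sem_dpd_A
280,48.87,0.23,44.00,0.34
290,47.79,0.21,42.45,0.38
295,46.20,0.23,39.89,0.27
300,43.30,0.19,37.59,0.36
305,37.75,0.20,33.15,0.22
310,31.43,0.14,26.13,0.14
315,28.41,0.04,22.37,0.07
320,27.38,0.04,20.88,0.04
330,26.78,0.03,19.98,0.02
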