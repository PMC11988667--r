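area,n,C16:0,C16:1,C17:0,C17:1,C18:0,C18:1,C18:2,C18:3,C20:0,C20:1,SFA,MUFA,PUFA,PUFA/SFA
Mexico,10,10.15,3.16,0.03,0.06,2.10,73.24,10.36,0.48,0.21,0.21,12.49,76.67,10.85,0.91
New Zealand,8,13.89,3.96,0.05,0.10,1.38,68.75,10.78,0.65,0.22,0.21,15.55,73.02,11.44,0.74
France,7,13.46,3.56,0.05,0.09,1.76,68.27,11.75,0.58,0.26,0.21,15.54,72.13,12.33,0.81
Australia,3,15.36,5.89,0.04,0.09,0.50,67.61,9.71,0.52,0.10,0.17,16.00,73.77,10.23,0.65
USA,2,16.71,5.95,0.05,0.10,1.15,63.57,11.46,0.69,0.16,0.17,18.07,69.79,12.14,0.69
Spain,2,12.90,2.35,0.07,0.12,2.43,69.85,11.08,0.59,0.36,0.26,15.76,72.57,11.67,0.74
Kenya,2,11.44,4.13,0.04,0.06,1.98,65.50,15.75,0.72,0.20,0.18,13.66,69.87,16.47,1.31
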