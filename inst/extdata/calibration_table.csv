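analyte,slope,intercept,range_low,range_high,r_squared,loq_ug_ml,lod_ug_ml,stability_rsd,precision_rsd,repeatability_rsd,recovery_mean,recovery_rsd
cynaroside,13.984,-3.0103,2.86,143.00,0.9997,0.0091,0.0046,0.85,0.75,2.10,98.52,0.62
narirutin,14.502,-4.3899,21.74,1088.00,0.9996,0.0150,0.0076,0.20,0.72,1.54,99.09,1.10
apigenin-7-O-glucuronide,12.039,-44.602,3.98,199.00,0.9995,0.0820,0.0270,1.24,0.74,1.97,101.74,0.87
rosmarinic acid,17.283,-34.682,3.70,195.00,0.9996,0.0170,0.0065,0.66,0.78,1.82,102.62,0.87
buddleoside,2.4643,-1.4829,2.60,160.00,0.9995,0.0450,0.0180,0.45,0.70,1.57,98.51,0.42
luteolin,6.3739,-3.0096,1.14,57.00,0.9996,0.2800,0.1400,1.97,2.89,2.52,100.04,0.55
isosakuranetin-7-O-rutinoside,8.5706,1.4295,21.52,1076.00,0.9995,0.0160,0.0081,0.22,0.76,1.54,101.17,1.81
naringenin,20.834,-0.4984,1.40,70.00,0.9995,0.0270,0.0130,0.65,0.94,1.08,98.28,1.03
apigenin,11.296,-1.6736,1.26,63.00,0.9996,0.0410,0.0170,0.57,0.95,2.14,99.72,1.05
buddlejasaponin IVb,14.782,-4.4511,1.01,101.00,0.9998,0.0140,0.0070,2.48,1.86,2.22,101.31,1.40
isosakuranetin,22.297,-4.2959,2.00,100.00,0.9996,0.0240,0.0089,0.21,0.74,1.03,97.30,0.85
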