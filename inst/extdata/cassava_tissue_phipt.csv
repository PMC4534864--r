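tissue_pair,enzyme,condition,cultivar,phipt
Ylv-Mlv,HpaII,field,Kibandameno,0.208
Ylv-Mlv,HpaII,field,Mzungu,0.000
Ylv-Mlv,HpaII,field,Mfaransa,NA
Ylv-Mlv,HpaII,field,Kizimbani,0.171
Ylv-Mlv,HpaII,field,Kiroba,0.259
Ylv-Mlv,HpaII,in_vitro,Kibandameno,0.070
Ylv-Mlv,HpaII,in_vitro,Mzungu,0.042
Ylv-Mlv,HpaII,in_vitro,Mfaransa,0.112
Ylv-Mlv,HpaII,in_vitro,Kizimbani,0.000
Ylv-Mlv,HpaII,in_vitro,Kiroba,0.178
Ylv-Mlv,MspI,field,Kibandameno,0.237
Ylv-Mlv,MspI,field,Mzungu,0.239
Ylv-Mlv,MspI,field,Mfaransa,NA
Ylv-Mlv,MspI,field,Kizimbani,0.114
Ylv-Mlv,MspI,field,Kiroba,0.260
Ylv-Mlv,MspI,in_vitro,Kibandameno,0.000
Ylv-Mlv,MspI,in_vitro,Mzungu,0.192
Ylv-Mlv,MspI,in_vitro,Mfaransa,0.209
Ylv-Mlv,MspI,in_vitro,Kizimbani,0.071
Ylv-Mlv,MspI,in_vitro,Kiroba,0.118
Ylv-Rt,HpaII,field,Kibandameno,0.447
Ylv-Rt,HpaII,field,Mzungu,0.000
Ylv-Rt,HpaII,field,Mfaransa,0.401
Ylv-Rt,HpaII,field,Kizimbani,0.142
Ylv-Rt,HpaII,field,Kiroba,0.264
Ylv-Rt,HpaII,in_vitro,Kibandameno,0.296
Ylv-Rt,HpaII,in_vitro,Mzungu,0.162
Ylv-Rt,HpaII,in_vitro,Mfaransa,0.260
Ylv-Rt,HpaII,in_vitro,Kizimbani,0.272
Ylv-Rt,HpaII,in_vitro,Kiroba,0.098
Ylv-Rt,MspI,field,Kibandameno,0.308
Ylv-Rt,MspI,field,Mzungu,0.461
Ylv-Rt,MspI,field,Mfaransa,0.538
Ylv-Rt,MspI,field,Kizimbani,0.654
Ylv-Rt,MspI,field,Kiroba,0.250
Ylv-Rt,MspI,in_vitro,Kibandameno,0.197
Ylv-Rt,MspI,in_vitro,Mzungu,0.178
Ylv-Rt,MspI,in_vitro,Mfaransa,0.148
Ylv-Rt,MspI,in_vitro,Kizimbani,0.286
Ylv-Rt,MspI,in_vitro,Kiroba,0.090
Mlv-Rt,HpaII,field,Kibandameno,0.196
Mlv-Rt,HpaII,field,Mzungu,0.108
Mlv-Rt,HpaII,field,Mfaransa,NA
Mlv-Rt,HpaII,field,Kizimbani,0.263
Mlv-Rt,HpaII,field,Kiroba,0.357
Mlv-Rt,HpaII,in_vitro,Kibandameno,0.301
Mlv-Rt,HpaII,in_vitro,Mzungu,0.344
Mlv-Rt,HpaII,in_vitro,Mfaransa,0.408
Mlv-Rt,HpaII,in_vitro,Kizimbani,0.139
Mlv-Rt,HpaII,in_vitro,Kiroba,0.201
Mlv-Rt,MspI,field,Kibandameno,0.049
Mlv-Rt,MspI,field,Mzungu,0.459
Mlv-Rt,MspI,field,Mfaransa,NA
Mlv-Rt,MspI,field,Kizimbani,0.550
Mlv-Rt,MspI,field,Kiroba,0.344
Mlv-Rt,MspI,in_vitro,Kibandameno,0.362
Mlv-Rt,MspI,in_vitro,Mzungu,0.386
Mlv-Rt,MspI,in_vitro,Mfaransa,0.375
Mlv-Rt,MspI,in_vitro,Kizimbani,0.250
Mlv-Rt,MspI,in_vitro,Kiroba,0.212
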