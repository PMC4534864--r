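variety,up_in_vitro,up_in_field
Mfaransa,185,1844
Mzungu,16021,17888
Kizimbani,2245,23438
Kiroba,1918,1380
Kibandameno,5068,12634
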