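gear_code,gear_name,n_metiers,n_vessels,n_trips,n_hauls
DRB,Bivalve dredges,7,3,1062,2153
FPO,Traps,63,103,44799,57261
GNS,Gillnets,81,107,28576,38508
GTR,Trammel nets,93,111,52563,75888
LLD,Drifting longline,12,28,556,879
LLS,Bottom longline,51,64,18094,22392
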