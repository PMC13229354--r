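gear_code,name,target,n_hauls,detail,season,area,depth,sediment,status,source
DRB,Solid surf clam bivalve dredges,SVE,1759,30,All year,NW,Shallow,Sand,literature,published study
FPO,Common octopus traps,OCC,48390,8-50 or none,Autumn to Winter,NW,Shallow,Sand and Mixed,literature,published study
FPO,Pouting traps,BIB,2697,50,Spring to Summer,NW,Shallow,Sand and Mixed,interview,interviews (4)
FPO,Norway lobster traps,NEP,2461,30-50,Summer to Autumn,CW; SW,Medium to Deep,Mud and Sand,literature,published study
FPO,European conger traps,COE,2038,50,Spring to Summer,NW,Shallow,Mixed and Rock,interview,interviews (3)
GNS,European hake gillnets,HKE,20069,100,Spring to Summer,NW,Shallow to Medium,Sand,literature,published study
GNS,Pouting gillnets,BIB,6526,60,Summer,NW,Shallow,Mixed,literature,published study
GNS,Atlantic horse mackerel gillnets,HOM,2698,,,,,,unvalidated,
GNS,Monkfish gillnets,MNZ,2533,220,Spring to Autumn,S,Shallow to Medium,Sand,literature,published study
GNS,Soles gillnets,SOL,1692,60,Autumn to Winter,NW; SW; S,Shallow,Sand,literature,published study
GNS,John Dories gillnets,JOD,972,200,Summer,NW,Shallow,Sand and Rock,interview,interviews (1)
GTR,Soles trammel nets,SOL,15269,80-100,Winter,NW,Shallow,Sand and Mixed,literature,published study
GTR,John Dories trammel nets,JOD,13273,200,Summer,NW; SW,Shallow,Sand and Rock,onboard,on-board observation
GTR,Monkfish trammel nets,MNZ,11474,220,Spring to Summer,NW; CW; SW,Shallow to Medium,Sand,literature,published study
GTR,European hake trammel nets,HKE,9740,,,,,,unvalidated,
GTR,Skates trammel nets,SKA,5586,220,Summer and Winter,NW,Shallow,Sand,literature,published study
GTR,Turbots trammel nets,TUR,3070,200,Winter to Spring,NW,Shallow,Sand and Mixed,onboard,on-board observation
GTR,Common octopus trammel nets,OCC,2808,,,,,,unvalidated,
GTR,Common cuttlefish trammel nets,CTC,2665,80-100,Autumn to Winter,NW,Shallow,Sand and Mixed,literature,published study
GTR,Pouting trammel nets,BIB,2503,,,,,,unvalidated,
GTR,European seabass trammel nets,BSS,1982,80,Winter,NW; CW,Shallow,Sand and Mixed,interview,interviews (2)
GTR,Atlantic horse mackerel trammel nets,HOM,1888,,,,,,unvalidated,
LLD,Swordfish drifting longline,SWO,380,16/0 and 17/0,Autumn,CW; SW,Deep,Unknown,literature,published study
LLD,Blue shark drifting longlines,BSH,310,16/0 and 17/0,Summer,NW,Shallow and Deep,Sand and Unknown,literature,published study
LLD,Black scabbardfish drifting longlines,BSF,149,,,,,,unvalidated,
LLS,Black scabbardfish bottom longlines,BSF,15652,5-8,All year,CW,Deep,Unknown,literature,published study
LLS,European conger bottom longlines,COE,990,3-8,Summer,NW,Shallow and Deep,Rock,interview,interviews (6)
LLS,Wreckfish bottom longlines,WRF,954,6-7,Spring to Summer,CW,Medium to Deep,Sand and Unknown,literature,published study
LLS,Silver scabbardfish bottom longlines,SFS,849,9,Summer,CW,Medium,Sand and Rock,interview,interviews (2)
LLS,Blackspot seabream bottom longlines,SBR,810,8-9,Autumn to Winter,CW,Medium,Sand and Rock,onboard,on-board observation
LLS,Smooth-hound bottom longlines,SDV,598,,,,,,unvalidated,
LLS,European hake bottom longlines,HKE,590,7-9,Spring,NW; CW,Shallow to Medium,Mud and Sand,literature,published study
LLS,Red porgy bottom longlines,RPG,482,8-9,Summer to Autumn,CW,Shallow,Sand and Rock,interview,interviews (1)
LLS,Blackbelly rosefish bottom longlines,BRF,387,3-5,Spring to Summer,CW; SW; S,Medium to Deep,Sand and Unknown,interview,interviews (4)
LLS,Skates bottom longlines,SKA,300,,,,,,unvalidated,
LLS,Alfonsinos bottom longlines,ALF,214,6,Winter to Spring,CW; SW,Medium to Deep,Sand and Unknown,interview,interviews (1)
LLS,Forkbeard bottom longlines,GFB,178,,,,,,unvalidated,
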