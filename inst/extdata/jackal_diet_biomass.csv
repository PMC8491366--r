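level,taxon,category,bio_cool_dry,bio_hot_dry,bio_total
category,ungulate,ungulate,39.3,41.9,40.7
item,muntjac,ungulate,21.6,18.7,20.1
item,wild_pig,ungulate,17.7,22.8,20.3
item,large_cervid,ungulate,0.0,0.4,0.2
item,civet,civet,21.8,12.9,17.2
item,hare,hare,8.1,1.3,4.6
item,porcupine,porcupine,0.0,0.2,0.1
item,small_rodent,small_rodent,6.8,5.3,6.0
item,bird,bird,1.7,4.8,3.3
category,reptile,reptile,0.7,2.1,1.4
item,small_lizard,reptile,0.3,0.6,0.4
item,small_snake,reptile,0.1,0.1,0.1
item,small_tortoise,reptile,0.0,0.0,0.0
item,unidentifiable_reptile,reptile,0.3,1.4,0.9
category,arthropod,arthropod,21.2,31.5,26.6
item,termite,arthropod,20.4,30.4,25.6
item,beetle,arthropod,0.1,0.7,0.4
item,grasshopper,arthropod,0.0,0.0,0.0
item,freshwater_crab,arthropod,0.8,0.4,0.6
item,egg_shell,egg_shell,0.0,0.0,0.0
item,seeds,seeds,0.3,0.0,0.1
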