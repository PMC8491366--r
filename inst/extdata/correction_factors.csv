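taxon,cf,category
muntjac,118,ungulate
wild_pig,84,ungulate
large_cervid,118,ungulate
civet,50,civet
hare,50,hare
porcupine,50,porcupine
small_rodent,23,small_rodent
bird,35,bird
small_lizard,18,reptile
small_snake,18,reptile
small_tortoise,18,reptile
unidentifiable_reptile,18,reptile
termite,12,arthropod
beetle,5,arthropod
grasshopper,5,arthropod
freshwater_crab,5,arthropod
egg_shell,15,egg_shell
seeds,14,seeds
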