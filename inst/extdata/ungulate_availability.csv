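species,density_per_km2,adult_female_mass_kg
banteng,2.3,600
muntjac,2.1,20
wild_pig,6.5,75
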