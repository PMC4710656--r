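pattern,trait_group
big body,BodySizeAndGrowth
large body,BodySizeAndGrowth
body size,BodySizeAndGrowth
live weight,BodySizeAndGrowth
heavy,BodySizeAndGrowth
fast growth,BodySizeAndGrowth
growth rate,BodySizeAndGrowth
grows fast,BodySizeAndGrowth
lamb growth,BodySizeAndGrowth
small body,BodySizeAndGrowth
light weight,BodySizeAndGrowth
slow growth,BodySizeAndGrowth
fat cover,Condition
good condition,Condition
body condition,Condition
poor condition,Condition
always fat,Condition
thin,Condition
lean,Condition
much milk,MilkProduction
milk yield,MilkProduction
good milk,MilkProduction
little milk,MilkProduction
low milk,MilkProduction
milk,MilkProduction
twinning,ReproductionAndMotheringAbility
twins,ReproductionAndMotheringAbility
lamb survival,ReproductionAndMotheringAbility
lambs survive,ReproductionAndMotheringAbility
good mother,ReproductionAndMotheringAbility
mothering,ReproductionAndMotheringAbility
fertile,ReproductionAndMotheringAbility
lambs every year,ReproductionAndMotheringAbility
poor mother,ReproductionAndMotheringAbility
loses lambs,ReproductionAndMotheringAbility
barren,ReproductionAndMotheringAbility
drought,DroughtTolerance
survives drought,DroughtTolerance
walks far for water,DroughtTolerance
needs little water,DroughtTolerance
disease,DiseaseResistance
resistant to disease,DiseaseResistance
worms,DiseaseResistance
parasite,DiseaseResistance
never sick,DiseaseResistance
often sick,DiseaseResistance
colour,BreedAttributes
color,BreedAttributes
legs,BreedAttributes
hoofs,BreedAttributes
hooves,BreedAttributes
breed type,BreedAttributes
red coat,BreedAttributes
white coat,BreedAttributes
long fat tail,BreedAttributes
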