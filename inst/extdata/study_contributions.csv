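quality,site,breed,trait_group,c1,c2,c3
Best,Amboseli,RedMaasai,BodySizeAndGrowth,6,4,3
Best,Amboseli,RedMaasai,Condition,0,4,3
Best,Amboseli,RedMaasai,MilkProduction,3,4,1
Best,Amboseli,RedMaasai,ReproductionAndMotheringAbility,9,4,0
Best,Amboseli,RedMaasai,DroughtTolerance,6,0,0
Best,Amboseli,RedMaasai,DiseaseResistance,0,0,0
Best,Amboseli,RedMaasai,BreedAttributes,0,0,1
Best,Isinya,RedMaasai,BodySizeAndGrowth,12,8,3
Best,Isinya,RedMaasai,Condition,0,0,0
Best,Isinya,RedMaasai,MilkProduction,3,4,4
Best,Isinya,RedMaasai,ReproductionAndMotheringAbility,0,4,2
Best,Isinya,RedMaasai,DroughtTolerance,9,2,0
Best,Isinya,RedMaasai,DiseaseResistance,3,8,1
Best,Isinya,RedMaasai,BreedAttributes,3,0,0
Best,Amboseli,Dorper,BodySizeAndGrowth,12,6,1
Best,Amboseli,Dorper,Condition,3,2,0
Best,Amboseli,Dorper,MilkProduction,3,0,2
Best,Amboseli,Dorper,ReproductionAndMotheringAbility,0,2,0
Best,Amboseli,Dorper,DroughtTolerance,0,0,0
Best,Amboseli,Dorper,DiseaseResistance,0,0,0
Best,Amboseli,Dorper,BreedAttributes,0,2,3
Best,Isinya,Dorper,BodySizeAndGrowth,18,10,2
Best,Isinya,Dorper,Condition,0,0,0
Best,Isinya,Dorper,MilkProduction,0,2,4
Best,Isinya,Dorper,ReproductionAndMotheringAbility,3,2,0
Best,Isinya,Dorper,DroughtTolerance,0,0,0
Best,Isinya,Dorper,DiseaseResistance,0,0,0
Best,Isinya,Dorper,BreedAttributes,0,0,1
Best,Amboseli,Cross,BodySizeAndGrowth,12,2,4
Best,Amboseli,Cross,Condition,3,4,0
Best,Amboseli,Cross,MilkProduction,3,6,3
Best,Amboseli,Cross,ReproductionAndMotheringAbility,6,4,0
Best,Amboseli,Cross,DroughtTolerance,3,2,1
Best,Amboseli,Cross,DiseaseResistance,0,0,0
Best,Amboseli,Cross,BreedAttributes,3,2,2
Best,Isinya,Cross,BodySizeAndGrowth,21,4,3
Best,Isinya,Cross,Condition,0,0,0
Best,Isinya,Cross,MilkProduction,0,8,2
Best,Isinya,Cross,ReproductionAndMotheringAbility,0,4,2
Best,Isinya,Cross,DroughtTolerance,3,0,0
Best,Isinya,Cross,DiseaseResistance,0,0,1
Best,Isinya,Cross,BreedAttributes,0,0,0
Poor,Amboseli,RedMaasai,BodySizeAndGrowth,3,0,3
Poor,Amboseli,RedMaasai,Condition,9,2,2
Poor,Amboseli,RedMaasai,MilkProduction,3,6,0
Poor,Amboseli,RedMaasai,ReproductionAndMotheringAbility,0,6,1
Poor,Amboseli,RedMaasai,DroughtTolerance,0,0,0
Poor,Amboseli,RedMaasai,DiseaseResistance,3,0,0
Poor,Amboseli,RedMaasai,BreedAttributes,0,2,0
Poor,Isinya,RedMaasai,BodySizeAndGrowth,9,2,5
Poor,Isinya,RedMaasai,Condition,3,0,0
Poor,Isinya,RedMaasai,MilkProduction,6,8,2
Poor,Isinya,RedMaasai,ReproductionAndMotheringAbility,0,0,0
Poor,Isinya,RedMaasai,DroughtTolerance,0,2,0
Poor,Isinya,RedMaasai,DiseaseResistance,6,0,0
Poor,Isinya,RedMaasai,BreedAttributes,0,2,0
Poor,Amboseli,Dorper,BodySizeAndGrowth,3,0,0
Poor,Amboseli,Dorper,Condition,0,0,2
Poor,Amboseli,Dorper,MilkProduction,0,6,2
Poor,Amboseli,Dorper,ReproductionAndMotheringAbility,6,4,0
Poor,Amboseli,Dorper,DroughtTolerance,0,0,0
Poor,Amboseli,Dorper,DiseaseResistance,9,0,0
Poor,Amboseli,Dorper,BreedAttributes,0,0,0
Poor,Isinya,Dorper,BodySizeAndGrowth,0,0,2
Poor,Isinya,Dorper,Condition,0,0,0
Poor,Isinya,Dorper,MilkProduction,6,6,2
Poor,Isinya,Dorper,ReproductionAndMotheringAbility,3,2,0
Poor,Isinya,Dorper,DroughtTolerance,0,0,1
Poor,Isinya,Dorper,DiseaseResistance,3,2,0
Poor,Isinya,Dorper,BreedAttributes,0,0,0
Poor,Amboseli,Cross,BodySizeAndGrowth,3,0,2
Poor,Amboseli,Cross,Condition,0,6,1
Poor,Amboseli,Cross,MilkProduction,3,4,4
Poor,Amboseli,Cross,ReproductionAndMotheringAbility,3,2,2
Poor,Amboseli,Cross,DroughtTolerance,3,0,1
Poor,Amboseli,Cross,DiseaseResistance,3,4,0
Poor,Amboseli,Cross,BreedAttributes,0,0,0
Poor,Isinya,Cross,BodySizeAndGrowth,0,4,3
Poor,Isinya,Cross,Condition,0,0,0
Poor,Isinya,Cross,MilkProduction,15,0,3
Poor,Isinya,Cross,ReproductionAndMotheringAbility,0,2,2
Poor,Isinya,Cross,DroughtTolerance,0,2,0
Poor,Isinya,Cross,DiseaseResistance,6,0,1
Poor,Isinya,Cross,BreedAttributes,0,0,0
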