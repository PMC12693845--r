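participant_id,item_id,frequency_per_day,portion_g,energy_per_100g
P001,spinach,1.0,80,23
P001,carrot,2.0,60,41
P001,apple,1.5,100,52
P001,walnut,1.0,10,654
P001,salmon,0.5,120,208
P001,rice,3.0,150,130
P001,tofu,1.0,100,76
P001,milk,1.0,200,61
P001,beef,0.5,120,250
P001,olive_oil_item,0.2,5,884
P002,spinach,0.5,80,23
P002,apple,0.5,100,52
P002,salmon,1.0,120,208
P002,rice,2.0,150,130
P002,tofu,0.5,100,76
P002,milk,2.0,200,61
P002,beef,1.5,120,250
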