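item_id,group
spinach,vegetables
carrot,vegetables
apple,fruits_nuts
walnut,fruits_nuts
salmon,fish
rice,cereals
tofu,legumes
milk,dairy
beef,meat
olive_oil_item,olive_oil
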