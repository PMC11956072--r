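code	pct_adolescent	pct_adult
grain_based_staple_foods	97.3	97.4
whole_grains	22.1	18.2
roots_and_tubers	32.8	31.8
pulses_legumes	41.3	41.3
nuts_and_seeds	18.2	21.2
vitamin_a_rich_orange_vegetables	43.6	44.4
dark_green_leafy_vegetables	64.5	70.5
other_vegetables	71.4	75.4
vitamin_a_rich_fruits	29.9	29.8
citrus_fruits	23.6	34.1
other_fruits	60.5	59.0
eggs	64.1	61.6
cheese	10.8	8.2
yogurt	6.7	9.7
milk	25.3	23.2
poultry	48.4	45.1
fish_and_seafood	60.3	63.3
unprocessed_red_meat_ruminants	22.8	24.4
unprocessed_red_meat_non_ruminants	34.0	43.1
processed_meats	33.4	22.2
baked_grain_based_sweets	41.8	37.5
other_sweets	42.0	26.6
salty_snacks	26.9	14.0
instant_noodles	44.3	35.2
deep_fried_foods	33.2	28.7
fast_foods	4.6	4.9
sweet_tea_coffee_cocoa	41.5	43.7
fruit_juice_fruit_flavoured_drinks	25.9	21.6
soft_drinks_and_energy_sports_drinks	29.4	25.7
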