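"society_id","region","subsistence_class","page_count","pub_year","female_coauthor","v_adultery","v_religious","v_food","v_rape","v_war_cowardice","p_reputational","p_material","p_physical","p_execution","c_adultery_reputational","c_adultery_material","c_adultery_physical","c_adultery_execution","c_religious_reputational","c_religious_material","c_religious_physical","c_religious_execution","c_food_reputational","c_food_material","c_food_physical","c_food_execution","c_rape_reputational","c_rape_material","c_rape_physical","c_rape_execution","c_war_cowardice_reputational","c_war_cowardice_material","c_war_cowardice_physical","c_war_cowardice_execution","external_trade","animal_husbandry","dependence_hunting","food_storage","community_size","social_stratification"
"alpha","Africa","hunter-gatherers",120,1931,0,1,0,0,0,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,4,0,2,0
"bravo","Asia","pastoralists",340,1965,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,NA,3,1,1,5,1
"charlie","Oceania","agriculturalists",85,1948,0,1,1,0,0,0,0,1,0,1,0,0,0,1,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,4,0,1,6,1
"delta","S America","horticulturalists",210,1978,0,0,0,1,0,0,0,1,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,0,0,0,0,0,1,1,2,NA,NA,0
"echo","N America","hunter-gatherers",55,1922,1,0,0,0,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,0,0,0,0,3,0,1,0
"foxtrot","Europe","other",160,1990,0,1,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,0,1,2,1,1,4,NA
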