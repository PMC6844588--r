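stratum,variable,level,count
urban_men,total,,3838
urban_women,total,,3918
rural_men,total,,5866
rural_women,total,,5997
urban_men,entry_state,no_disability,2145
urban_men,entry_state,mild_disability,1064
urban_men,entry_state,severe_disability,629
urban_women,entry_state,no_disability,1574
urban_women,entry_state,mild_disability,1464
urban_women,entry_state,severe_disability,880
rural_men,entry_state,no_disability,3169
rural_men,entry_state,mild_disability,2042
rural_men,entry_state,severe_disability,655
rural_women,entry_state,no_disability,2260
rural_women,entry_state,mild_disability,2702
rural_women,entry_state,severe_disability,1035
urban_men,marital,married,2142
urban_men,exercise,yes,2028
urban_women,exercise,yes,1490
rural_men,exercise,yes,1600
rural_women,exercise,yes,1124
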