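study_id,region,population,n,years,tier_p50_stat,tier_p95_stat,tier_max_stat,moe_overall_p50,moe_overall_p95,moe_overall_max
Roca_2014,ES-Valencia,children,125,2010,P50,P95,max,1201,320,33
Fernandez_2017_children,ES-Valencia,children,568,2016,P50,P95,max,3504,357,39
Suarez_2021,ES-Andalusia,adolescents,117,2017-2019,P50,P95,max,247500,58929,4091
Llop_2017,ES-Valencia,pregnant_women,573,2003-2006,P50,P95,max,12122,1800,51
Fernandez_2020_lactating,ES-Valencia,lactating_women,116,2015,P50,P95,max,2970,752,354
Gari_2018_adults,ES-Catalonia,adults,80,,geomean,,max,2475,,675
Gari_2018_farmworkers,ES-Catalonia,farm_workers,45,,geomean,,max,1414,,297
PT_INSEF,Portugal,adults,296,2019-2020,P50,P95,upper_ci_p95,3193,808,710
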