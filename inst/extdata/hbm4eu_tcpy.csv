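study_id,country,population,years,n,p50,p95,upper_ci_p95,max,adjusted
BE_3xG,Belgium,children,2014-2020,,1.22,3.24,5.05,,FALSE
CY_Organiko,Cyprus,children,2014-2020,,6.52,13.82,15.74,,FALSE
FR_Esteban_children,France,children,2014-2020,,n.r.,n.r.,n.r.,,FALSE
IL_RAVMABAT_children,Israel,children,2014-2020,,2.80,18.38,28.84,,FALSE
SI_SLOCRP,Slovenia,children,2014-2020,,0.61,3.08,4.92,,FALSE
NL_SPECIMEN,Netherlands,children,2014-2020,,1.13,3.49,5.55,,FALSE
FR_ESTEBAN_adults,France,adults,2014-2021,,n.r.,n.r.,0.06,,FALSE
DE_ESB,Germany,adults,2014-2021,,0.82,2.87,3.87,,FALSE
IS_Diet_HBM,Iceland,adults,2014-2021,,0.61,2.07,3.30,,FALSE
IL_RAVMABAT_adults,Israel,adults,2014-2021,,2.75,11.22,55.22,,FALSE
PT_INSEF,Portugal,adults,2014-2021,,1.86,7.35,8.37,,FALSE
CH_Study,Switzerland,adults,2014-2021,,0.97,3.64,4.72,,FALSE
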