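"name","family","form","layer","mw","gene","partners"
"PopZ_m","PopZ","monomer","cyto",19.2,"popZ",NA
"PopZ_p","PopZ","polymer","cyto",NA,NA,NA
"PodJL_m","PodJL","monomer","cyto",102,"podJ",NA
"PodJL_p","PodJL","polymer","cyto",NA,NA,NA
"PodJS_m","PodJS","monomer","cyto",85,NA,NA
"PodJS_p","PodJS","polymer","cyto",NA,NA,NA
"SpmX_m","SpmX","monomer","cyto",46.5,"spmX",NA
"SpmX_p","SpmX","polymer","cyto",NA,NA,NA
"PerP","PerP","plain","cyto",24,"perP",NA
"DivK","DivK","plain","cyto",14,"divK",NA
"DivKp","DivK","phospho","cyto",14,NA,NA
"DivK_b","DivK","plain","membrane",NA,NA,NA
"DivKp_b","DivK","phospho","membrane",NA,NA,NA
"DivJ","DivJ","plain","cyto",66,"divJ",NA
"DivJ_b","DivJ","plain","membrane",NA,NA,NA
"DivJ_DivK","DivJ","complex","cyto",80,NA,"DivJ;DivK"
"DivJ_DivK_b","DivJ","complex","membrane",NA,NA,"DivJ;DivK"
"DivJ_DivKp","DivJ","complex","cyto",80,NA,"DivJ;DivKp"
"DivJ_DivKp_b","DivJ","complex","membrane",NA,NA,"DivJ;DivKp"
"PleC_ph","PleC","plain","cyto",92,"pleC",NA
"PleC_ph_b","PleC","plain","membrane",NA,NA,NA
"PleC_kin","PleC","plain","cyto",92,NA,NA
"PleC_kin_b","PleC","plain","membrane",NA,NA,NA
"PleC_DivKp","PleC","complex","cyto",106,NA,"PleC_ph;DivKp"
"PleC_DivKp_b","PleC","complex","membrane",NA,NA,"PleC_ph;DivKp"
"DivL","DivL","plain","cyto",85,"divL",NA
"DivL_b","DivL","plain","membrane",NA,NA,NA
"DivL_DivKp","DivL","complex","cyto",99,NA,"DivL;DivKp"
"DivL_DivKp_b","DivL","complex","membrane",NA,NA,"DivL;DivKp"
"CckA_kin","CckA","plain","cyto",76,"cckA",NA
"CckA_kin_b","CckA","plain","membrane",NA,NA,NA
"CckA_ph","CckA","plain","cyto",76,NA,NA
"CckA_ph_b","CckA","plain","membrane",NA,NA,NA
"CpdR_u","CpdR","plain","cyto",25,"cpdR",NA
"CpdR_u_b","CpdR","plain","membrane",NA,NA,NA
"CpdRp","CpdR","phospho","cyto",25,NA,NA
"CpdRp_b","CpdR","phospho","membrane",NA,NA,NA
"CtrA_u","CtrA","plain","cyto",26,"ctrA",NA
"CtrAp","CtrA","phospho","cyto",26,NA,NA
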