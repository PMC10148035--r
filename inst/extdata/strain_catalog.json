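{"WT":{"name":"WT","set":[],"scale":[],"zring_enabled":true,"sim_duration_override":null},"dpodJ":{"name":"dpodJ","set":{"k_s_PodJ":0,"k_s_PodJ2":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"dpopZ":{"name":"dpopZ","set":{"k_s_PopZ":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"dspmX":{"name":"dspmX","set":{"k_s_SpmX":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"dspmX_filament":{"name":"dspmX_filament","set":{"k_s_SpmX":0},"scale":[],"zring_enabled":false,"sim_duration_override":750},"ddivJ":{"name":"ddivJ","set":{"k_s_DivJ":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"divJ_H338A":{"name":"divJ_H338A","set":{"k_ph_DivJ":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"dpleC":{"name":"dpleC","set":{"k_s_PleC":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"pleC_H610A":{"name":"pleC_H610A","set":{"k_cat_PleC":0,"k_kin_PleC":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"pleC_F778L":{"name":"pleC_F778L","set":{"k_kin_PleC":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"delocalized_PleC":{"name":"delocalized_PleC","set":{"k_fb_PleC":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"delocalized_DivL":{"name":"delocalized_DivL","set":{"alpha_DivLPodJ":0},"scale":[],"zring_enabled":true,"sim_duration_override":null},"PodJ_op1":{"name":"PodJ_op1","set":[],"scale":{"k_s_PodJ":3,"k_s_PodJ2":3},"zring_enabled":true,"sim_duration_override":null},"PodJ_op2":{"name":"PodJ_op2","set":[],"scale":{"k_s_PodJ":10,"k_s_PodJ2":10},"zring_enabled":true,"sim_duration_override":null},"PopZ_op":{"name":"PopZ_op","set":[],"scale":{"k_s_PopZ":5},"zring_enabled":true,"sim_duration_override":null}}
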