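visit_id,chm_id,chm_name,chm_type,dose_g_per_day,duration_days,admin_per_day
V000001,jwxys,Jia-Wei-Xiao-Yao-San,HF,4.87,7,3
V000001,cyperus,Cyperus rotundus L.,SH,1.38,7,3
V000002,jwxys,Jia-Wei-Xiao-Yao-San,HF,4.5,5,3
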