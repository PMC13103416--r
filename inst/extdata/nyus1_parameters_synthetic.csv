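cultivar,percentile,param_name,value,source
Cabernet-Sauvignon,10,ch_max,-21,synthetic
Cabernet-Sauvignon,10,ch_init,-8,synthetic
Cabernet-Sauvignon,10,acc_rate,0.06,synthetic
Cabernet-Sauvignon,10,acc_t0,12,synthetic
Cabernet-Sauvignon,10,acc_t1,10,synthetic
Cabernet-Sauvignon,10,acc_tk,30,synthetic
Cabernet-Sauvignon,10,deacc_rate,1.6,synthetic
Cabernet-Sauvignon,10,deacc_mid,11,synthetic
Cabernet-Sauvignon,10,deacc_b,0.35,synthetic
Cabernet-Sauvignon,10,dp_mid,55,synthetic
Cabernet-Sauvignon,10,dp_slope,0.09,synthetic
Cabernet-Sauvignon,50,ch_max,-24,synthetic
Cabernet-Sauvignon,50,ch_init,-10,synthetic
Cabernet-Sauvignon,50,acc_rate,0.06,synthetic
Cabernet-Sauvignon,50,acc_t0,12,synthetic
Cabernet-Sauvignon,50,acc_t1,10,synthetic
Cabernet-Sauvignon,50,acc_tk,30,synthetic
Cabernet-Sauvignon,50,deacc_rate,1.6,synthetic
Cabernet-Sauvignon,50,deacc_mid,11,synthetic
Cabernet-Sauvignon,50,deacc_b,0.35,synthetic
Cabernet-Sauvignon,50,dp_mid,55,synthetic
Cabernet-Sauvignon,50,dp_slope,0.09,synthetic
Cabernet-Sauvignon,90,ch_max,-27,synthetic
Cabernet-Sauvignon,90,ch_init,-12,synthetic
Cabernet-Sauvignon,90,acc_rate,0.06,synthetic
Cabernet-Sauvignon,90,acc_t0,12,synthetic
Cabernet-Sauvignon,90,acc_t1,10,synthetic
Cabernet-Sauvignon,90,acc_tk,30,synthetic
Cabernet-Sauvignon,90,deacc_rate,1.6,synthetic
Cabernet-Sauvignon,90,deacc_mid,11,synthetic
Cabernet-Sauvignon,90,deacc_b,0.35,synthetic
Cabernet-Sauvignon,90,dp_mid,55,synthetic
Cabernet-Sauvignon,90,dp_slope,0.09,synthetic
Riesling,10,ch_max,-24,synthetic
Riesling,10,ch_init,-8.5,synthetic
Riesling,10,acc_rate,0.08,synthetic
Riesling,10,acc_t0,12,synthetic
Riesling,10,acc_t1,10,synthetic
Riesling,10,acc_tk,30,synthetic
Riesling,10,deacc_rate,2,synthetic
Riesling,10,deacc_mid,10.5,synthetic
Riesling,10,deacc_b,0.35,synthetic
Riesling,10,dp_mid,50,synthetic
Riesling,10,dp_slope,0.1,synthetic
Riesling,50,ch_max,-27,synthetic
Riesling,50,ch_init,-10.5,synthetic
Riesling,50,acc_rate,0.08,synthetic
Riesling,50,acc_t0,12,synthetic
Riesling,50,acc_t1,10,synthetic
Riesling,50,acc_tk,30,synthetic
Riesling,50,deacc_rate,2,synthetic
Riesling,50,deacc_mid,10.5,synthetic
Riesling,50,deacc_b,0.35,synthetic
Riesling,50,dp_mid,50,synthetic
Riesling,50,dp_slope,0.1,synthetic
Riesling,90,ch_max,-30,synthetic
Riesling,90,ch_init,-12.5,synthetic
Riesling,90,acc_rate,0.08,synthetic
Riesling,90,acc_t0,12,synthetic
Riesling,90,acc_t1,10,synthetic
Riesling,90,acc_tk,30,synthetic
Riesling,90,deacc_rate,2,synthetic
Riesling,90,deacc_mid,10.5,synthetic
Riesling,90,deacc_b,0.35,synthetic
Riesling,90,dp_mid,50,synthetic
Riesling,90,dp_slope,0.1,synthetic
Concord,10,ch_max,-27,synthetic
Concord,10,ch_init,-9,synthetic
Concord,10,acc_rate,0.1,synthetic
Concord,10,acc_t0,13,synthetic
Concord,10,acc_t1,10,synthetic
Concord,10,acc_tk,30,synthetic
Concord,10,deacc_rate,3,synthetic
Concord,10,deacc_mid,10,synthetic
Concord,10,deacc_b,0.4,synthetic
Concord,10,dp_mid,45,synthetic
Concord,10,dp_slope,0.12,synthetic
Concord,50,ch_max,-30,synthetic
Concord,50,ch_init,-11,synthetic
Concord,50,acc_rate,0.1,synthetic
Concord,50,acc_t0,13,synthetic
Concord,50,acc_t1,10,synthetic
Concord,50,acc_tk,30,synthetic
Concord,50,deacc_rate,3,synthetic
Concord,50,deacc_mid,10,synthetic
Concord,50,deacc_b,0.4,synthetic
Concord,50,dp_mid,45,synthetic
Concord,50,dp_slope,0.12,synthetic
Concord,90,ch_max,-33,synthetic
Concord,90,ch_init,-13,synthetic
Concord,90,acc_rate,0.1,synthetic
Concord,90,acc_t0,13,synthetic
Concord,90,acc_t1,10,synthetic
Concord,90,acc_tk,30,synthetic
Concord,90,deacc_rate,3,synthetic
Concord,90,deacc_mid,10,synthetic
Concord,90,deacc_b,0.4,synthetic
Concord,90,dp_mid,45,synthetic
Concord,90,dp_slope,0.12,synthetic
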