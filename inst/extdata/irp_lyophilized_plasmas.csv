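irp_id,plasma_id,pt_mean_s,sd_log_pt,n,mnpt_s,sd_log_mnpt,m,isi,sd_isi
rTF/16,Lyo A,12.17,0.021,10,12.17,0.014,6,1.11,0.063
rTF/16,Lyo B,25.25,0.0090,10,12.17,0.014,6,1.11,0.063
rTF/16,Lyo C,36.64,0.011,10,12.17,0.014,6,1.11,0.063
rTF/16,Lyo D,56.46,0.020,10,12.17,0.014,6,1.11,0.063
IRP 24/114,Lyo A,10.69,0.016,10,11.28,0.016,2,1.08,0.030
IRP 24/114,Lyo B,19.80,0.016,10,11.28,0.016,2,1.08,0.030
IRP 24/114,Lyo C,29.38,0.016,10,11.28,0.016,2,1.08,0.030
IRP 24/114,Lyo D,41.70,0.017,10,11.28,0.016,2,1.08,0.030
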