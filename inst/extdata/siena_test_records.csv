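record,n_items,duration_hms,patient,recording,n_seizures,n_predicted_raw,n_predicted_cal,far_raw,far_cal,reduction_pct,duration_hours
1,2217,1:50:51,8,2,1,1,0,2.7,0,100,1.8475
2,2388,1:59:24,10,2,1,1,1,4.8,0,100,1.99
3,2604,4:22:27,11,3,1,1,0,4.2,0,100,4.3741666667
4,5249,4:22:27,11,4,1,1,1,6.6,0,100,4.3741666667
5,2957,2:27:51,12,2,3,3,1,5.8,2.1,64,2.4641666667
6,2803,2:20:09,13,2,1,1,1,5.7,0,100,2.3358333333
7,2754,2:17:42,14,2,1,1,1,9.1,1.6,83,2.295
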