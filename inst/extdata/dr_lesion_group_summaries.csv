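index,group,n,mean,sd
hemorrhage_total_area_px,group1,39,921.05,1319.560
hemorrhage_total_area_px,group2,29,15218.59,17031.178
hemorrhage_total_area_px,group3,23,16479.22,15613.505
hemorrhage_count,group1,39,3.26,2.702
hemorrhage_count,group2,29,26.62,17.551
hemorrhage_count,group3,23,11.35,9.384
hemorrhage_max_area_px,group1,39,636.03,1021.743
hemorrhage_max_area_px,group2,29,3595.55,3211.929
hemorrhage_max_area_px,group3,23,7133.70,7550.703
exudate_total_area_px,group1,39,1496.46,2699.786
exudate_total_area_px,group2,29,6589.90,10347.651
exudate_total_area_px,group3,23,15062.87,18862.476
exudate_count,group1,39,6.00,10.665
exudate_count,group2,29,20.66,26.203
exudate_count,group3,23,11.96,14.729
exudate_max_area_px,group1,39,578.87,1363.809
exudate_max_area_px,group2,29,1622.69,3186.810
exudate_max_area_px,group3,23,7084.78,8306.680
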