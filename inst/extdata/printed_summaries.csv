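table,quantity,printed,note
volume_bbch48,mean_measured,0.0029,
volume_bbch48,mean_calculated,0.0027,
volume_bbch48,mean_detected,0.0025,
volume_bbch48,sd_pct_measured,19.89,
volume_bbch48,sd_pct_calculated,22.5,
volume_bbch48,sd_pct_detected,30.8,
volume_bbch48,accuracy_calculated,87.2,accuracy formula undocumented in source; mean relative accuracy on the rounded column gives 86.6
volume_bbch48,accuracy_detected,86.7,relative to the calculated column
volume_bbch45,mean_measured,0.00092,
volume_bbch45,mean_calculated,0.00083,
volume_bbch45,mean_detected,0.00078,
volume_bbch45,sd_pct_measured,30.06,
volume_bbch45,sd_pct_calculated,25.31,
volume_bbch45,sd_pct_detected,41.2,
volume_bbch45,accuracy_calculated,84.9,
volume_bbch45,accuracy_detected,84.33,relative to the calculated column
leafarea_bbch48,mean_leaves_visible,13.9,
leafarea_bbch48,mean_measured_la,0.68,
leafarea_bbch48,mean_calculated_la,0.65,column mean is 0.661; printed summary likely from unrounded source data
leafarea_bbch48,mean_leaves_detected,12.7,column mean is 12.8
leafarea_bbch48,mean_detected_la,0.61,
leafarea_bbch48,sd_pct_leaves_visible,10.8,
leafarea_bbch48,sd_pct_measured_la,12.7,
leafarea_bbch48,sd_pct_calculated_la,15.12,
leafarea_bbch48,sd_pct_leaves_detected,11.7,
leafarea_bbch48,sd_pct_detected_la,17.7,
leafarea_bbch48,accuracy_calculated,90.9,
leafarea_bbch48,accuracy_detected,94.1,relative to the calculated column
leafarea_bbch48,area_per_leaf_measured,0.049,mean measured LA over mean visible leaf count
leafarea_bbch45,mean_leaves_visible,19.4,
leafarea_bbch45,mean_measured_la,0.73,
leafarea_bbch45,mean_calculated_la,0.72,
leafarea_bbch45,mean_leaves_detected,16.2,
leafarea_bbch45,mean_detected_la,0.61,
leafarea_bbch45,sd_pct_leaves_visible,9.56,
leafarea_bbch45,sd_pct_measured_la,20.21,
leafarea_bbch45,sd_pct_calculated_la,16.24,
leafarea_bbch45,sd_pct_leaves_detected,14.8,
leafarea_bbch45,sd_pct_detected_la,20.95,
leafarea_bbch45,accuracy_calculated,90.3,
leafarea_bbch45,accuracy_detected,84.9,relative to the calculated column
leafarea_bbch45,area_per_leaf_measured,0.037,
leafarea_bbch41,mean_leaves_visible,17.1,
leafarea_bbch41,mean_measured_la,0.19,column mean is 0.200
leafarea_bbch41,mean_calculated_la,0.19,
leafarea_bbch41,mean_leaves_detected,15.3,column mean is 14.2
leafarea_bbch41,mean_detected_la,0.18,summary row printed as 18.1; decimal misprint for 0.18 (column mean 0.180)
leafarea_bbch41,sd_pct_leaves_visible,12.5,
leafarea_bbch41,sd_pct_measured_la,9.2,
leafarea_bbch41,sd_pct_calculated_la,15.9,
leafarea_bbch41,sd_pct_leaves_detected,10.1,
leafarea_bbch41,sd_pct_detected_la,21.4,
leafarea_bbch41,accuracy_calculated,91.7,
leafarea_bbch41,accuracy_detected,87.6,relative to the calculated column
leafarea_bbch41,area_per_leaf_measured,0.0117,narrative quotes 0.02 per leaf; table columns give 0.200/17.1
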