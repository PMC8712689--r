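descriptor,code,M01,M04,M09,M14
stem_area_cm2,St_A,1.45,1.48,1.21,2.36
parenchyma_area_pct,Pa_A,71.9,81.7,80.3,71.5
rind_area_pct,Ri_A,21.2,13.3,13.0,20.2
bundle_area_pct,Vb_A,8.2,6.2,6.9,8.7
bundle_density_per_cm2,Vb_D,63.4,81.7,116.6,62.1
bundle_mean_area_mm2,Vi_A,0.130,0.076,0.059,0.141
bundle_elongation,Vi_E,0.777,0.802,0.738,0.790
middle_parenchyma_mean_size_um,Pm_Cd,70.0,81.8,65.5,64.2
middle_parenchyma_sd_um,Pm_Cs,27.9,31.6,29.1,29.4
near_rind_parenchyma_mean_size_um,Pr_Cd,57.9,54.9,46.0,56.2
near_rind_parenchyma_sd_um,Pr_Cs,31.6,30.6,27.4,34.9
middle_parenchyma_wall_density_pct,Pm_CD,4.29,3.67,4.58,4.67
near_rind_parenchyma_wall_density_pct,Pr_CD,5.18,5.46,6.53,5.36
total_cell_wall_pct_stem,CW_T,32.7,23.1,24.1,32.4
middle_parenchyma_wall_pct_cw,Pm_Cw,6.3,8.8,10.1,7.7
near_rind_parenchyma_wall_pct_cw,Pr_Cw,3.9,6.3,7.4,3.1
rind_wall_pct_cw,Ri_Cw,65.3,58.6,56.4,63.2
bundle_wall_pct_cw,Vb_Cw,25.3,27.0,28.6,26.8
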