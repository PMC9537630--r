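variable,label,kind,g0_mean,g0_sd,g1_mean,g1_sd,g0_count,g1_count,g0_median,g0_q1,g0_q3,g1_median,g1_q1,g1_q3,p_printed
sex_male,"Gender, male",binary,,,,,43,16,,,,,,,0.314
age_y,Age (y),normal,50.43,10.59,55.97,8.49,,,,,,,,,0.012
height_cm,Height (cm),normal,163.44,8.0,162.42,8.5,,,,,,,,,0.562
weight_kg,Weight (kg),normal,64.28,10.41,63.42,9.0,,,,,,,,,0.693
bmi,BMI,normal,23.96,2.65,23.99,2.44,,,,,,,,,0.971
dm,Diabetes mellitus,binary,,,,,3,0,,,,,,,0.550
chd,Coronary heart disease,binary,,,,,5,5,,,,,,,0.277
rf,Renal failure,binary,,,,,2,0,,,,,,,1.000
hypertension,Hypertension,binary,,,,,16,11,,,,,,,0.200
stroke,Stroke,binary,,,,,0,1,,,,,,,0.310
hyperlipidemia,Hyperlipidemia,binary,,,,,2,3,,,,,,,0.171
beta_blocker,Beta-receptor blocker,binary,,,,,11,9,,,,,,,0.130
ccb,Calcium channel blocker,binary,,,,,12,3,,,,,,,0.381
statin,Statin,binary,,,,,4,3,,,,,,,0.674
anticoagulant,Anticoagulant,binary,,,,,3,3,,,,,,,0.371
amiodarone,Amiodarone,binary,,,,,0,0,,,,,,,
digoxin,Digoxin,binary,,,,,4,1,,,,,,,1.000
acei_arb,ACEI or ARB,binary,,,,,12,4,,,,,,,0.770
diuretics,Diuretics,binary,,,,,38,20,,,,,,,0.376
la_mm,Left atrium diameter (mm),normal,40.06,7.63,46,11.94,,,,,,,,,0.015
ra_mm,Right atrium diameter (mm),normal,35.32,5.54,37.48,11.15,,,,,,,,,0.312
lvef_pct,LVEF (%),normal,62.57,9.35,59.97,12.45,,,,,,,,,0.251
cre_umol_l,Creatinine (umol/L),normal,76.59,15.12,81.87,12.89,,,,,,,,,0.123
gfr,GFR (ml/min/1.73 m2),normal,93.00,13.81,82.02,14.94,,,,,,,,,0.001
urea_mmol_l,Urea (mmol/L),normal,5.59,1.32,6.40,1.75,,,,,,,,,0.012
alt_iu_l,ALT (IU/L),normal,21.64,16.16,21.23,9.87,,,,,,,,,0.896
ast_iu_l,AST (IU/L),normal,20.90,9.10,22.00,5.25,,,,,,,,,0.532
alp_iu_l,ALP (IU/L),normal,78.91,34.31,83.42,30.71,,,,,,,,,0.532
tg_mmol_l,Triglyceride (mmol/L),normal,1.47,1.01,1.55,1.04,,,,,,,,,0.715
cho_mmol_l,Cholesterol (mmol/L),normal,4.58,1.04,4.39,0.82,,,,,,,,,0.352
surgery_time_h,Surgery time (h),skewed,,,,,,,4,3,4.5,4,3,4.5,0.634
cpb_min,Cardiopulmonary bypass (min),skewed,,,,,,,110,85,133.5,110,96,137,0.474
acc_min,Aortic cross-clamp (min),skewed,,,,,,,73,60,103.5,78,59,108,0.864
mech_vent_h,Mechanical ventilation time (h),skewed,,,,,,,33,18.5,47,52,34,88,0.001
single_valve,Single valve surgery,binary,,,,,34,7,,,,,,,0.012
multi_valve,Multiple valve surgery,binary,,,,,15,17,,,,,,,0.001
cabg,CABG,binary,,,,,4,3,,,,,,,0.674
aortic_replacement,Aortic replacement,binary,,,,,17,4,,,,,,,0.183
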